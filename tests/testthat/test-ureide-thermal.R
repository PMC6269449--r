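test_that("RAU follows the 4-to-1 ureide-N weighting", {
  expect_equal(compute_rau(1, 0), 100)
  expect_equal(compute_rau(1, 4), 50)   # 4U = N forces one half
  expect_equal(compute_rau(2, 24), 25)  # 8/(8+24)
  expect_equal(compute_rau(0, 1), 0)    # nitrate-only limit
})

test_that("RAU rejects undefined and out-of-domain inputs", {
  expect_error(compute_rau(0, 0), class = "bnf_undefined_rau_error")
  expect_error(compute_rau(-1, 2), class = "bnf_domain_error")
  expect_error(compute_rau(1, -0.1), class = "bnf_domain_error")
})

test_that("RAU is scale-invariant and monotone in each concentration", {
  set.seed(11)
  for (i in 1:25) {
    u <- runif(1, 0.01, 50); n <- runif(1, 0.01, 200); k <- runif(1, 0.1, 100)
    expect_equal(compute_rau(k * u, k * n), compute_rau(u, n))
    eps <- 1e-6
    expect_gt(compute_rau(u + eps, n), compute_rau(u, n))
    expect_lt(compute_rau(u, n + eps), compute_rau(u, n))
  }
})

test_that("thermal time accumulates daily means above base, clamped at zero", {
  w1 <- data.frame(date = as.Date("2016-06-01"), tmax_c = 30, tmin_c = 20)
  expect_equal(accumulate_thermal_time(w1, base_temp = 8), 17)
  w2 <- data.frame(date = as.Date("2016-06-01"), tmax_c = 10, tmin_c = 4)
  expect_equal(accumulate_thermal_time(w2, base_temp = 8), 0) # mean 7 < base
  w3 <- flat_weather("2016-06-01", 10, inc = 12)
  expect_equal(accumulate_thermal_time(w3), 120)
})

test_that("thermal time is additive and ignores sub-base days", {
  w <- flat_weather("2016-06-01", 30, inc = 17)
  total <- accumulate_thermal_time(w)
  part1 <- accumulate_thermal_time(w, start = "2016-06-01", end = "2016-06-14")
  part2 <- accumulate_thermal_time(w, start = "2016-06-15", end = "2016-06-30")
  expect_equal(part1 + part2, total)
  # appending cold days (daily mean at the base) changes nothing
  cold <- flat_weather("2016-07-01", 5, inc = 0)
  expect_equal(accumulate_thermal_time(rbind(w, cold)), total)
})

test_that("gaps in the weather record are reported with the missing dates", {
  w <- flat_weather("2016-06-01", 10)[-4, ]
  err <- expect_error(accumulate_thermal_time(w), class = "bnf_weather_gap_error")
  expect_match(conditionMessage(err), "2016-06-04")
})

test_that("stage thermal times are anchored at the origin and ordered", {
  w <- flat_weather("2016-06-01", 40, inc = 17)
  clk <- thermal_clock(w, origin_date = "2016-06-05")
  tts <- stage_thermal_times(clk, c(V2 = "2016-06-05", V4 = "2016-06-10",
                                    R2 = "2016-06-15"))
  expect_equal(unname(tts[["V2"]]), 0)
  expect_equal(tts[["R2"]] - tts[["V4"]], 85) # 5 days x 17 degCd
  expect_true(all(diff(tts) >= 0))
  expect_error(stage_thermal_times(clk, c(V1 = "2016-06-01")),
               class = "bnf_stage_order_error")
})

test_that("readers reject unknown labels with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site_id = "s1", treatment = c("control", "N_late"),
                       block = 1, stage = "R6", ureide_conc = 1, nitrate_conc = 1),
            path, row.names = FALSE)
  err <- expect_error(read_assay_csv(path), class = "bnf_label_error")
  expect_match(conditionMessage(err), "line\\(s\\) 3")
  expect_match(conditionMessage(err), "N_late")
})

test_that("weather reader enforces tmax >= tmin", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(date = "2016-06-01", tmax_c = 10, tmin_c = 15),
            path, row.names = FALSE)
  expect_error(read_weather_csv(path), class = "bnf_schema_error")
})
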