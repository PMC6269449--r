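high_ctrl <- c(rau_max = 90, t_m = 397, t_max = 1117)
med_ctrl <- c(rau_max = 84, t_m = 362, t_max = 1066)
low_ctrl <- c(rau_max = 71, t_m = 0, t_max = 931)

test_that("beta curve hits its anchors: 0 at origin, peak at t_max", {
  for (p in list(high_ctrl, med_ctrl, low_ctrl)) {
    expect_equal(beta_rau(0, p[1], p[2], p[3]), 0)
    expect_equal(beta_rau(p[["t_max"]], p[1], p[2], p[3]), unname(p[["rau_max"]]))
  }
  # published half-max point of the high-BNF control curve
  expect_equal(beta_rau(473, 90, 397, 1117), 45, tolerance = 0.1 / 45)
  expect_error(beta_rau(100, 90, 500, 500), class = "bnf_degenerate_params_error")
})

test_that("beta curve rises on (0, t_max) and declines just past t_max", {
  tt <- seq(10, 1117, by = 10)
  v <- beta_rau(tt, 90, 397, 1117)
  expect_true(all(diff(v) > 0))
  expect_lt(beta_rau(1200, 90, 397, 1117), 90)
})

test_that("the rate curve is the derivative of the RAU curve", {
  params <- list(high_ctrl, med_ctrl, low_ctrl, c(80, 300, 1000))
  for (p in params) {
    # central-difference oracle at interior points
    for (t0 in c(0.25, 0.5, 0.75, 1.1) * p[[3]]) {
      h <- 1e-3
      num <- (beta_rau(t0 + h, p[1], p[2], p[3]) -
                beta_rau(t0 - h, p[1], p[2], p[3])) / (2 * h)
      expect_equal(rau_rate(t0, p[1], p[2], p[3]), num, tolerance = 1e-6)
    }
    expect_equal(rau_rate(p[[3]], p[1], p[2], p[3]), 0) # zero at the peak
    expect_lt(rau_rate(1.2 * p[[3]], p[1], p[2], p[3]), 0) # decline beyond
  }
})

test_that("closed-form maximum rate equals the rate curve at t_m", {
  for (p in list(high_ctrl, med_ctrl, low_ctrl, c(60, 100, 800))) {
    mr <- max_rate(p[1], p[2], p[3])
    expect_equal(rau_rate(p[[2]], p[1], p[2], p[3]), mr, tolerance = 1e-9)
    expect_equal(max_rate(2 * p[1], p[2], p[3]), 2 * mr) # linear in rau_max
  }
})

test_that("derived traits reproduce the published group-curve values", {
  expect_equal(max_rate(90, 397, 1117), 0.1169, tolerance = 0.001 / 0.1169)
  expect_equal(max_rate(84, 362, 1066), 0.1138, tolerance = 0.001 / 0.1138)
  expect_equal(t_half(90, 397, 1117), 473, tolerance = 3 / 473)
  expect_equal(t_half(84, 362, 1066), 444, tolerance = 3 / 444)
  expect_equal(t_half(71, 0, 931), 272, tolerance = 5 / 272)
})

test_that("t_half is the half-max root and lies inside (0, t_max)", {
  set.seed(21)
  for (i in 1:20) {
    tmx <- runif(1, 600, 1400)
    p <- c(runif(1, 40, 100), runif(1, 0, 0.8) * tmx, tmx)
    th <- t_half(p[1], p[2], p[3])
    expect_gt(th, 0); expect_lt(th, p[3])
    expect_equal(beta_rau(th, p[1], p[2], p[3]) / p[1], 0.5, tolerance = 1e-9)
  }
})

test_that("AUC matches adaptive quadrature and obeys its bounds", {
  for (p in list(high_ctrl, low_ctrl)) {
    for (t_end in c(800, 1500, 1800)) {
      a <- auc_beta(p[1], p[2], p[3], t_end)
      oracle <- stats::integrate(function(t) pmax(0, beta_rau(t, p[1], p[2], p[3])),
                                 0, t_end, rel.tol = 1e-10, subdivisions = 500)$value
      expect_equal(a$raw, oracle, tolerance = 1e-6)
      expect_lte(a$raw, p[[1]] * t_end) # rectangle bound
    }
  }
  expect_equal(auc_beta(0, 300, 1000, 1500)$raw, 0)
  a <- auc_beta(90, 397, 1117, 1500, reference = auc_beta(90, 397, 1117, 1500)$raw)
  expect_equal(a$rel, 1) # self-normalisation
  expect_error(auc_beta(90, 397, 1117, -5), class = "bnf_domain_error")
})

test_that("fitting noise-free beta data recovers the generator exactly", {
  tt <- seq(100, 1600, by = 100)
  rau <- beta_rau(tt, 80, 300, 1000)
  fit <- fit_beta(tt, rau)
  expect_equal(unname(fit$coef), c(80, 300, 1000), tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("degenerate inputs are refused, never silently fitted", {
  expect_error(fit_beta(c(100, 500, 900, 1300), rep(50, 4)),
               class = "bnf_degenerate_data_error")
  expect_error(fit_beta(c(100, 500, 900), c(10, 50, 80)),
               class = "bnf_insufficient_data_error")
})

test_that("multi-site noisy refits cover the truth at their stated SEs", {
  # 4 stages x 12 sites with seasons spread over 900-1500 degCd,
  # plot noise SD 12 -- the network design the curve fits face
  set.seed(101)
  tts <- stage_grid(seq(900, 1500, length.out = 12))
  truth <- med_ctrl
  n_rep <- 200
  covered <- matrix(NA, n_rep, 3)
  for (i in seq_len(n_rep)) {
    rau <- beta_rau(tts, truth[1], truth[2], truth[3]) + rnorm(length(tts), 0, 12)
    f <- fit_beta(tts, rau)
    covered[i, ] <- abs(f$coef - truth) <= 2 * f$se
  }
  expect_true(all(colMeans(covered) >= 0.90))
})

test_that("AICc matches its closed form", {
  expect_equal(aicc(48, 480, 4), 48 * log(10) + 8 + 2 * 4 * 5 / 43)
  expect_error(aicc(7, 10, 7), class = "bnf_insufficient_data_error")
})

test_that("identical data prefer one shared curve", {
  set.seed(31)
  tt <- stage_grid(seq(1000, 1300, length.out = 12))
  obs <- data.frame(t = tt, rau = beta_rau(tt, 84, 362, 1066) + rnorm(length(tt), 0, 8))
  cmp <- compare_fits_aicc(obs, obs)
  expect_equal(cmp$preferred, "shared")
  expect_gte(cmp$evidence_ratio, 1)
})

test_that("well-separated peak RAU is detected as separate curves", {
  set.seed(32)
  tt <- stage_grid(seq(1000, 1300, length.out = 12))
  n_sep <- 0
  for (i in 1:100) {
    a <- data.frame(t = tt, rau = beta_rau(tt, 90, 397, 1117) + rnorm(length(tt), 0, 2))
    b <- data.frame(t = tt, rau = beta_rau(tt, 50, 397, 1117) + rnorm(length(tt), 0, 2))
    cmp <- compare_fits_aicc(a, b)
    n_sep <- n_sep + (cmp$preferred == "separate")
  }
  expect_gte(n_sep, 95)
})
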