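test_that("noise-free broken-stick data are recovered exactly and continuously", {
  x <- seq(900, 1700, length.out = 41) # includes 1200, the true breakpoint
  a <- 2; b <- 100; d <- -1; tto <- 1200
  y <- ifelse(x < tto, a * x + b, a * tto + b + d * (x - tto))
  fit <- fit_bilinear(x, y)
  expect_equal(fit$a, a, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_equal(fit$d, d, tolerance = 1e-6)
  expect_equal(fit$tt_o, tto)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-8)
})

test_that("constant traits give zero slopes and zero residuals", {
  x <- seq(1000, 1600, length.out = 30)
  fit <- fit_bilinear(x, rep(4.2, 30))
  expect_equal(fit$a, 0, tolerance = 1e-10)
  expect_equal(fit$d, 0, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
})

test_that("the two segments join continuously at the fitted breakpoint", {
  set.seed(41)
  for (i in 1:15) {
    x <- sort(runif(40, 900, 1700))
    y <- 3 * x - 1000 * (runif(1) < 0.5) + rnorm(40, 0, 50)
    fit <- fit_bilinear(x, y)
    left <- fit$a * fit$tt_o + fit$b
    right <- predict(fit, fit$tt_o)
    expect_equal(left, right, tolerance = 1e-9 * diff(range(y)))
  }
})

test_that("breakpoint is recovered under trial-scale noise", {
  # 92 points (23 sites x 4 treatments), V-shaped trend, noise 5% of range
  x <- seq(900, 1700, length.out = 92)
  step <- diff(x)[1]
  tto <- x[45]
  a <- -3; b <- 8000; d <- 11 / 3
  ytrue <- ifelse(x < tto, a * x + b, a * tto + b + d * (x - tto))
  sdn <- 0.05 * diff(range(ytrue))
  set.seed(303)
  hits <- 0
  for (i in 1:200) {
    fit <- fit_bilinear(x, ytrue + rnorm(92, 0, sdn))
    hits <- hits + (abs(fit$tt_o - tto) <= step + 1e-9)
  }
  expect_gte(hits / 200, 0.80)
})

test_that("de-trending is idempotent: residuals carry no phenology trend", {
  set.seed(42)
  x <- seq(900, 1700, length.out = 60)
  y <- ifelse(x < 1250, 4 * x, 4 * 1250 + 1.5 * (x - 1250)) + rnorm(60, 0, 80)
  fit <- fit_bilinear(x, y)
  # any straight-line trend in the residuals is exactly projected out
  lin <- lm(fit$residuals ~ x)
  scale <- diff(range(y)) / diff(range(x))
  expect_lt(abs(coef(lin)[["x"]]), 1e-8 * scale)
  # and a fresh broken-stick fit finds almost no structure left
  refit <- fit_bilinear(x, fit$residuals)
  expect_lt(refit$r2, 0.2)
})

test_that("mean residual regression recovers a constructed cost slope", {
  set.seed(43)
  rau <- runif(80, 45, 95)
  res <- -13 * (rau - mean(rau))
  reg <- suppressWarnings(residual_mean_regression(res, rau)) # exact fit by design
  expect_equal(reg$slope, -13, tolerance = 1e-9)
  expect_lt(reg$p_value, 1e-12)
})

test_that("a null relationship yields a slope within 2 SE of zero", {
  set.seed(44)
  rau <- runif(80, 45, 95)
  res <- rnorm(80, 0, 100)
  reg <- residual_mean_regression(res, rau)
  fit <- lm(res ~ rau)
  expect_lt(abs(reg$slope), 2 * summary(fit)$coefficients["rau", "Std. Error"])
  expect_error(residual_mean_regression(res, rep(50, 80)),
               class = "bnf_degenerate_data_error")
})

test_that("quantile lines reproduce an exact linear relationship at any tau", {
  rau <- seq(40, 95, length.out = 25)
  res <- -7 * rau + 300
  for (tau in c(0.01, 0.5, 0.99)) {
    q <- suppressWarnings(residual_quantile_regression(res, rau, tau))
    expect_equal(q$slope, -7, tolerance = 1e-9)
    expect_equal(q$intercept, 300, tolerance = 1e-6)
  }
  expect_error(residual_quantile_regression(res, rau, 1.2), class = "bnf_domain_error")
})

test_that("the median line tracks the mean line under symmetric noise", {
  set.seed(45)
  rau <- runif(120, 40, 95)
  res <- -10 * (rau - 67) + rnorm(120, 0, 30)
  q50 <- residual_quantile_regression(res, rau, 0.5)
  m <- residual_mean_regression(res, rau)
  expect_equal(q50$slope, m$slope, tolerance = 0.15)
})

test_that("boundary lines bracket the data and the mean line", {
  set.seed(46)
  rau <- runif(150, 40, 95)
  res <- -8 * (rau - 67) + rnorm(150, 0, 40)
  q99 <- residual_quantile_regression(res, rau, 0.99)
  q01 <- residual_quantile_regression(res, rau, 0.01)
  m <- residual_mean_regression(res, rau)
  grid <- seq(min(rau), max(rau), length.out = 50)
  up <- q99$intercept + q99$slope * grid
  lo <- q01$intercept + q01$slope * grid
  expect_true(all(up >= lo)) # no quantile crossing over the observed range
  fit99 <- q99$intercept + q99$slope * rau
  expect_gte(mean(res <= fit99 + 1e-9), 0.98) # on/above ~99% of points
  mid <- m$intercept + m$slope * grid
  expect_true(all(mid <= up + 1e-9 & mid >= lo - 1e-9))
})

test_that("heteroscedastic data give a steeper lower boundary than the mean", {
  # lower boundary constructed with 2.5x the mean slope
  set.seed(404)
  ratios <- numeric(15)
  for (i in seq_along(ratios)) {
    x <- runif(300, 40, 95)
    w <- 10 + 19.5 * (x - 40)
    y <- -13 * (x - 67.5) + runif(300, -1, 1) * w
    m <- residual_mean_regression(y, x)
    q <- residual_quantile_regression(y, x, 0.01)
    ratios[i] <- q$slope / m$slope
  }
  expect_gte(mean(ratios), 2)
  expect_lte(mean(ratios), 3)
})
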