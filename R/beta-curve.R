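#' The beta growth function for seasonal RAU
#'
#' Three-parameter beta growth function describing the seasonal trajectory
#' of the relative abundance of ureides on a thermal-time axis:
#' \deqn{RAU(t) = RAU_{max}\left(1 + \frac{t_{max}-t}{t_{max}-t_m}\right)
#'   \left(\frac{t}{t_{max}}\right)^{t_{max}/(t_{max}-t_m)}}
#' `rau_max` is the peak RAU, reached at thermal time `t_max`; `t_m` is the
#' thermal time of the maximum growth rate (the inflection). The curve is 0
#' at `t = 0`, rises sigmoidally to `rau_max` at `t_max`, and declines
#' beyond it. At `t_m = 0` the 0^0 terms are taken as 1 by continuous limit.
#'
#' @param t Thermal time from the V2 anchor (degCd), vectorised.
#' @param rau_max Peak RAU (percent), 0 < rau_max <= 100 (up to 110 during
#'   fitting).
#' @param t_m Thermal time of maximum rate (degCd), 0 <= t_m < t_max.
#' @param t_max Thermal time of peak RAU (degCd).
#' @return RAU in percent (can be negative far beyond `t_max`; the fitted
#'   range of interest is `[0, ~1.7 t_max]`).
#' @seealso [rau_rate()], [max_rate()], [t_half()], [fit_beta()]
#' @export
beta_rau <- function(t, rau_max, t_m, t_max) {
  check_beta_params(rau_max, t_m, t_max)
  t <- unname(t); rau_max <- unname(rau_max); t_m <- unname(t_m); t_max <- unname(t_max)
  ex <- t_max / (t_max - t_m)
  out <- rau_max * (1 + (t_max - t) / (t_max - t_m)) * (t / t_max)^ex
  out[t == 0] <- 0
  out
}

#' Rate of change of RAU with thermal time
#'
#' First derivative of [beta_rau()] with respect to thermal time, in the
#' max-rate-scaled form
#' \deqn{RAU'(t) = R_{max rate} \frac{t_{max}-t}{t_{max}-t_m}
#'   \left(\frac{t}{t_m}\right)^{t_m/(t_{max}-t_m)}}
#' It peaks at `t = t_m` (where it equals [max_rate()]), is zero at
#' `t = t_max`, and negative beyond (the late-season decline of fixation).
#'
#' @inheritParams beta_rau
#' @return Rate in percent per degCd.
#' @export
rau_rate <- function(t, rau_max, t_m, t_max) {
  check_beta_params(rau_max, t_m, t_max)
  t <- unname(t); rau_max <- unname(rau_max); t_m <- unname(t_m); t_max <- unname(t_max)
  ex <- t_m / (t_max - t_m)
  pw <- if (t_m == 0) rep(1, length(t)) else (t / t_m)^ex
  pw[t == 0 & t_m == 0] <- 1
  max_rate(rau_max, t_m, t_max) * (t_max - t) / (t_max - t_m) * pw
}

#' Maximum rate of RAU increase (closed form)
#'
#' The peak of [rau_rate()], attained at `t = t_m`:
#' \deqn{R_{max rate} = \frac{2t_{max}-t_m}{t_{max}(t_{max}-t_m)}
#'   \left(\frac{t_m}{t_{max}}\right)^{t_m/(t_{max}-t_m)} RAU_{max}}
#' At `t_m = 0` the power term is 1 (continuous limit).
#'
#' @inheritParams beta_rau
#' @return Maximum rate in percent per degCd.
#' @export
max_rate <- function(rau_max, t_m, t_max) {
  check_beta_params(rau_max, t_m, t_max)
  rau_max <- unname(rau_max); t_m <- unname(t_m); t_max <- unname(t_max)
  pw <- if (t_m == 0) 1 else (t_m / t_max)^(t_m / (t_max - t_m))
  (2 * t_max - t_m) / (t_max * (t_max - t_m)) * pw * rau_max
}

#' Thermal time at half-maximal RAU
#'
#' Finds `t0.5`, the unique thermal time in `(0, t_max)` where the fitted
#' curve reaches 50% of `rau_max`. Uniqueness follows from the strict
#' monotonicity of the beta function on `(0, t_max)`; the root is located
#' numerically to better than 1e-9 in normalised RAU.
#'
#' @inheritParams beta_rau
#' @return Thermal time in degCd.
#' @export
t_half <- function(rau_max, t_m, t_max) {
  check_beta_params(rau_max, t_m, t_max)
  f <- function(t) beta_rau(t, rau_max, t_m, t_max) / rau_max - 0.5
  uniroot(f, interval = c(1e-9 * t_max, t_max), tol = 1e-12)$root
}

#' Area under the seasonal RAU curve
#'
#' Integrates the positive part of the fitted curve from 0 to `t_end`
#' (typically the last sampled stage) by composite Simpson quadrature with
#' at least 1000 panels. The relative AUC normalises by a reference maximum
#' (the largest raw AUC in the data set), so the data-set maximum is
#' exactly 1.
#'
#' @inheritParams beta_rau
#' @param t_end Upper integration limit in degCd (> 0).
#' @param reference Optional data-set maximum raw AUC for normalisation.
#' @return List with `raw` (percent x degCd) and `rel` (dimensionless; `NA`
#'   if no `reference` is given).
#' @export
auc_beta <- function(rau_max, t_m, t_max, t_end, reference = NULL) {
  check_beta_params(rau_max, t_m, t_max)
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0) {
    bnf_error("t_end must be a positive scalar", "bnf_domain_error")
  }
  n_panels <- 2000L # even, >= 1000
  tt <- seq(0, t_end, length.out = n_panels + 1L)
  y <- pmax(0, beta_rau(tt, rau_max, t_m, t_max))
  h <- t_end / n_panels
  raw <- h / 3 * (y[1] + y[n_panels + 1] +
                    4 * sum(y[seq(2, n_panels, by = 2)]) +
                    2 * sum(y[seq(3, n_panels - 1, by = 2)]))
  rel <- if (is.null(reference)) NA_real_ else raw / reference
  list(raw = raw, rel = rel)
}

check_beta_params <- function(rau_max, t_m, t_max) {
  if (any(!is.finite(c(rau_max, t_m, t_max)))) {
    bnf_error("non-finite beta-curve parameters", "bnf_domain_error")
  }
  if (t_m >= t_max) {
    bnf_error("degenerate beta-curve parameters: t_m must be < t_max",
              "bnf_degenerate_params_error")
  }
  if (t_m < 0 || t_max <= 0) {
    bnf_error("beta-curve parameters require 0 <= t_m < t_max, t_max > 0",
              "bnf_domain_error")
  }
  invisible(TRUE)
}

#' Fit the beta growth function to RAU observations
#'
#' Unweighted nonlinear least squares for `(rau_max, t_m, t_max)` on
#' replicate-level observations (no pre-averaging), with Levenberg-Marquardt
#' iteration and box bounds `0 < rau_max <= 110`,
#' `0 <= t_m, t_max <= 1.5 max(t)`. Initial values: `rau_max` at the
#' largest observed RAU, `t_max` at its thermal time, `t_m` at 0.4 `t_max`
#' -- robust for sigmoidal trajectories sampled at four stages. Asymptotic
#' standard errors come from the Jacobian at the solution. Goodness of fit
#' is `r2 = 1 - SSE/SST` and `syx = sqrt(SSE/(n-3))`, the residual SD.
#'
#' @param t Thermal times (degCd) of the observations.
#' @param rau Observed RAU (percent), same length as `t`.
#' @param init Optional named start values `c(rau_max=, t_m=, t_max=)`.
#' @param t_end Upper limit for the derived AUC (defaults to `max(t)`).
#' @return An object of class `bnf_beta_fit`: estimates, standard errors,
#'   `r2`, `syx`, `n`, `sse`, convergence and boundary flags, fitted values
#'   and residuals, plus derived traits `max_rate`, `t_half` and `auc_raw`.
#' @export
fit_beta <- function(t, rau, init = NULL, t_end = NULL) {
  ok <- complete.cases(t, rau)
  t <- as.numeric(t[ok]); rau <- as.numeric(rau[ok])
  n <- length(t)
  if (n <= 3) bnf_error("fit_beta needs more than 3 observations", "bnf_insufficient_data_error")
  if (length(unique(t)) < 3) {
    bnf_error("fit_beta needs at least 3 distinct thermal times", "bnf_insufficient_data_error")
  }
  if (sd(rau) == 0) {
    bnf_error("all RAU values identical: beta curve is unidentifiable", "bnf_degenerate_data_error")
  }
  upper_t <- 1.5 * max(t)
  if (is.null(init)) {
    rau_max0 <- max(rau)
    t_max0 <- t[which.max(rau)]
    if (t_max0 <= 0) t_max0 <- 0.7 * max(t)
    init <- c(rau_max = min(rau_max0, 110), t_m = 0.4 * t_max0,
              t_max = min(t_max0, upper_t))
  }
  # safe model: finite large residuals where the optimiser proposes t_m >= t_max
  model <- function(rau_max, t_m, t_max) {
    if (t_m >= t_max - 1e-8) return(rep(1e6, n))
    ex <- t_max / (t_max - t_m)
    val <- rau_max * (1 + (t_max - t) / (t_max - t_m)) * (t / t_max)^ex
    val[t == 0] <- 0
    val
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rau ~ model(rau_max, t_m, t_max),
      start = as.list(init),
      lower = c(rau_max = 1e-6, t_m = 0, t_max = 1e-3),
      upper = c(rau_max = 110, t_m = upper_t, t_max = upper_t),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      bnf_error(sprintf("beta-curve fit failed: %s (start: rau_max=%.3g, t_m=%.3g, t_max=%.3g)",
                        conditionMessage(e), init[["rau_max"]], init[["t_m"]], init[["t_max"]]),
                "bnf_nonconvergence_error")
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(est)))
  fitted_vals <- beta_rau(t, est[["rau_max"]], est[["t_m"]], est[["t_max"]])
  res <- rau - fitted_vals
  sse <- sum(res^2)
  sst <- sum((rau - mean(rau))^2)
  at_bound <- est[["rau_max"]] > 110 - 1e-6 || est[["t_m"]] < 1e-9 ||
    est[["t_m"]] > upper_t - 1e-6 || est[["t_max"]] > upper_t - 1e-6
  t_end <- if (is.null(t_end)) max(t) else t_end
  structure(list(
    coef = est, se = se,
    r2 = 1 - sse / sst, syx = sqrt(sse / (n - 3)),
    n = n, sse = sse,
    converged = isTRUE(fit$convInfo$isConv) || fit$convInfo$stopCode %in% 1:4,
    boundary = at_bound,
    max_rate = max_rate(est[["rau_max"]], est[["t_m"]], est[["t_max"]]),
    t_half = t_half(est[["rau_max"]], est[["t_m"]], est[["t_max"]]),
    auc_raw = auc_beta(est[["rau_max"]], est[["t_m"]], est[["t_max"]], t_end)$raw,
    t_end = t_end,
    data = data.frame(t = t, rau = rau),
    fitted = fitted_vals, residuals = res
  ), class = "bnf_beta_fit")
}

#' @export
print.bnf_beta_fit <- function(x, ...) {
  cat("Beta growth-function fit (seasonal RAU)\n")
  cat(sprintf("  rau_max = %.2f (SE %.2f) %%\n", x$coef[["rau_max"]], x$se[["rau_max"]]))
  cat(sprintf("  t_m     = %.1f (SE %.1f) degCd\n", x$coef[["t_m"]], x$se[["t_m"]]))
  cat(sprintf("  t_max   = %.1f (SE %.1f) degCd\n", x$coef[["t_max"]], x$se[["t_max"]]))
  cat(sprintf("  derived: max rate %.4f %%/degCd, t0.5 %.0f degCd, AUC %.0f %%*degCd\n",
              x$max_rate, x$t_half, x$auc_raw))
  cat(sprintf("  n = %d, R2 = %.3f, Syx = %.2f, converged = %s%s\n",
              x$n, x$r2, x$syx, x$converged,
              if (x$boundary) " (parameter at bound)" else ""))
  invisible(x)
}

#' Small-sample AICc for a least-squares fit
#'
#' \deqn{AICc = n \ln(SSE/n) + 2k + \frac{2k(k+1)}{n-k-1}}
#' with the error variance counted as a parameter, the convention of
#' common curve-fitting software for nested-model comparisons.
#'
#' @param n Number of observations.
#' @param sse Residual sum of squares.
#' @param k Number of parameters including the error variance.
#' @return The AICc value.
#' @export
aicc <- function(n, sse, k) {
  if (n - k - 1 <= 0) {
    bnf_error("AICc undefined: need n > k + 1", "bnf_insufficient_data_error")
  }
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Shared-vs-separate curve comparison by AICc
#'
#' Tests whether two sets of RAU observations (e.g. control vs a nitrogen
#' treatment within a BNF group) are better described by one shared beta
#' curve or by separate curves. The shared model fits one parameter triple
#' to the pooled data (k = 4 with the error variance); the separate model
#' fits one triple per set (k = 7). Both AICc values are computed on the
#' pooled n; the smaller wins, and the evidence ratio `exp(|delta|/2)`
#' quantifies the support.
#'
#' @param obs_a,obs_b Data frames with columns `t` and `rau`.
#' @return List of class `bnf_aicc_comparison`: `aicc_shared`,
#'   `aicc_separate`, `delta` (`aicc_separate - aicc_shared`; negative
#'   favours separate curves), `preferred` (`"shared"` or `"separate"`),
#'   `evidence_ratio`, and the three underlying fits.
#' @export
compare_fits_aicc <- function(obs_a, obs_b) {
  for (obs in list(obs_a, obs_b)) {
    if (!is.data.frame(obs) || !all(c("t", "rau") %in% names(obs))) {
      bnf_error("observations must be data frames with columns t and rau",
                "bnf_schema_error")
    }
  }
  fit_a <- fit_beta(obs_a$t, obs_a$rau)
  fit_b <- fit_beta(obs_b$t, obs_b$rau)
  pooled <- rbind(obs_a[c("t", "rau")], obs_b[c("t", "rau")])
  fit_shared <- fit_beta(pooled$t, pooled$rau)
  n <- nrow(pooled)
  a_sh <- aicc(n, fit_shared$sse, k = 4)
  a_sep <- aicc(n, fit_a$sse + fit_b$sse, k = 7)
  delta <- a_sep - a_sh
  structure(list(
    aicc_shared = a_sh, aicc_separate = a_sep, delta = delta,
    preferred = if (a_sep < a_sh) "separate" else "shared",
    evidence_ratio = exp(abs(delta) / 2),
    fit_a = fit_a, fit_b = fit_b, fit_shared = fit_shared
  ), class = "bnf_aicc_comparison")
}

#' @export
print.bnf_aicc_comparison <- function(x, ...) {
  cat(sprintf("AICc comparison: shared %.2f vs separate %.2f -> prefer %s (evidence ratio %.1f)\n",
              x$aicc_shared, x$aicc_separate, x$preferred, x$evidence_ratio))
  invisible(x)
}
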