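#' Continuous bilinear (broken-stick) phenology model
#'
#' Multi-environment trials confound trait responses with phenology: longer
#' season length (thermal time to R6) drives yield, harvest index and seed
#' composition. This fits the continuous two-segment linear model
#' \deqn{Y = aX + b \quad (X < TT_o), \qquad
#'   Y = a\,TT_o + b + d\,(X - TT_o) \quad (X \ge TT_o)}
#' with left slope `a`, intercept `b`, right slope `d` and breakpoint
#' `tt_o`, continuous at the breakpoint by construction. The breakpoint is
#' profiled over the observed `x` values (excluding the two extremes at
#' each end): for each candidate the conditional model is linear and solved
#' by least squares, and the global SSE minimiser is returned. This search
#' is deterministic and exhaustive at the study's scale (~92 points); ties
#' go to the smallest candidate breakpoint.
#'
#' @param x Thermal time to R6 (degCd).
#' @param y Trait values (same length).
#' @return Object of class `bnf_bilinear_fit`: `a`, `b`, `d`, `tt_o`,
#'   `fitted`, `residuals`, `sse`, `r2`, `n`, and the candidate grid.
#' @export
fit_bilinear <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 6) bnf_error("fit_bilinear needs at least 6 points", "bnf_insufficient_data_error")
  ux <- sort(unique(x))
  if (length(ux) < 5) {
    bnf_error("fit_bilinear needs at least 5 distinct x values", "bnf_insufficient_data_error")
  }
  candidates <- ux[3:(length(ux) - 2)]
  candidates <- candidates[vapply(candidates, function(cc) {
    sum(x < cc) >= 3 && sum(x >= cc) >= 3
  }, logical(1))]
  if (!length(candidates)) {
    bnf_error("no interior breakpoint candidate with 3 points on each side",
              "bnf_degenerate_data_error")
  }
  best <- NULL
  for (tto in candidates) {
    hinge <- pmax(x - tto, 0)
    fit <- lm(y ~ x + hinge)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      cf <- coef(fit)
      best <- list(tt_o = tto, a = cf[["x"]], b = cf[["(Intercept)"]],
                   d = cf[["x"]] + cf[["hinge"]], sse = sse,
                   fitted = fit$fitted.values, residuals = fit$residuals)
    }
  }
  sst <- sum((y - mean(y))^2)
  structure(list(
    a = best$a, b = best$b, d = best$d, tt_o = best$tt_o,
    fitted = as.numeric(best$fitted), residuals = as.numeric(best$residuals),
    sse = best$sse, r2 = if (sst > 0) 1 - best$sse / sst else NA_real_,
    n = n, x = x, y = y, candidates = candidates
  ), class = "bnf_bilinear_fit")
}

#' Evaluate a bilinear fit at new x
#'
#' @param object A `bnf_bilinear_fit`.
#' @param newdata Optional numeric vector of x values.
#' @param ... Unused.
#' @return Predicted trait values.
#' @export
predict.bnf_bilinear_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  ifelse(x < object$tt_o,
         object$a * x + object$b,
         object$a * object$tt_o + object$b + object$d * (x - object$tt_o))
}

#' @export
print.bnf_bilinear_fit <- function(x, ...) {
  cat(sprintf("Bilinear phenology fit: a=%.4g, b=%.4g, d=%.4g, tt_o=%.0f degCd (n=%d, R2=%.3f)\n",
              x$a, x$b, x$d, x$tt_o, x$n, x$r2))
  invisible(x)
}

#' Mean regression of de-trended residuals on RAU at R6
#'
#' Ordinary least-squares regression of phenology-adjusted trait residuals
#' on RAU_R6, quantifying the mean cost of fixation (e.g. kg seed yield per
#' percent RAU_R6) after the phenology trend is removed.
#'
#' @param residuals De-trended trait residuals.
#' @param rau_r6 RAU at R6 (percent), same length.
#' @return A tibble with `tau = "mean"`, `slope`, `intercept`, `p_value`
#'   (two-sided, for slope = 0) and `n`.
#' @export
residual_mean_regression <- function(residuals, rau_r6) {
  ok <- complete.cases(residuals, rau_r6)
  r <- as.numeric(residuals[ok]); x <- as.numeric(rau_r6[ok])
  if (length(r) < 3) bnf_error("need at least 3 points", "bnf_insufficient_data_error")
  if (sd(x) == 0) bnf_error("rau_r6 has zero variance", "bnf_degenerate_data_error")
  fit <- lm(r ~ x)
  sm <- summary(fit)$coefficients
  tibble::tibble(tau = "mean",
                 slope = sm["x", "Estimate"],
                 intercept = sm["(Intercept)", "Estimate"],
                 p_value = sm["x", "Pr(>|t|)"],
                 n = length(r))
}

#' Quantile regression of residuals on RAU at R6 (boundary lines)
#'
#' Fits the line minimising the check loss
#' \eqn{\sum_i \rho_\tau(r_i - \alpha - \beta\,x_i)} with
#' \eqn{\rho_\tau(u) = u(\tau - 1\{u<0\})}. Extreme quantiles (0.99, 0.01)
#' trace the upper/lower boundaries of the residual-RAU relationship. The
#' optimum of this linear program is attained at a basic solution -- a line
#' through two data points -- so the solver enumerates all point pairs with
#' distinct x, evaluates the check loss for each, and returns the exact
#' minimiser. Ties are broken deterministically by pair order (sorted by x,
#' then y). Quadratic-in-n work, exact and reproducible at this study's
#' scale.
#'
#' @inheritParams residual_mean_regression
#' @param tau Quantile level in (0, 1).
#' @return A tibble with `tau`, `slope`, `intercept`, `p_value` (`NA`:
#'   no distribution theory is attached to the boundary lines), `n`, and
#'   attribute `loss` (the minimised check loss).
#' @export
residual_quantile_regression <- function(residuals, rau_r6, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    bnf_error("tau must be a single value in (0, 1)", "bnf_domain_error")
  }
  ok <- complete.cases(residuals, rau_r6)
  r <- as.numeric(residuals[ok]); x <- as.numeric(rau_r6[ok])
  n <- length(r)
  if (n < 20) bnf_error("quantile regression needs at least 20 points", "bnf_insufficient_data_error")
  if (n < 50) warning("fewer than 50 points: extreme quantile lines are unstable")
  if (sd(x) == 0) bnf_error("rau_r6 has zero variance", "bnf_degenerate_data_error")
  ord <- order(x, r)
  x <- x[ord]; r <- r[ord]
  pairs <- utils::combn(n, 2)
  dx <- x[pairs[2, ]] - x[pairs[1, ]]
  keep <- abs(dx) > 1e-12
  if (!any(keep)) bnf_error("all x identical", "bnf_degenerate_data_error")
  slopes <- (r[pairs[2, keep]] - r[pairs[1, keep]]) / dx[keep]
  intercepts <- r[pairs[1, keep]] - slopes * x[pairs[1, keep]]
  check_loss <- function(b, a) {
    u <- r - a - b * x
    sum(u * (tau - (u < 0)))
  }
  best_i <- 1L; best_loss <- Inf
  # chunked vectorised evaluation keeps memory bounded for large n
  m <- length(slopes)
  chunk <- 2000L
  for (s in seq(1L, m, by = chunk)) {
    idx <- s:min(s + chunk - 1L, m)
    U <- outer(r, rep(1, length(idx))) - outer(rep(1, n), intercepts[idx]) -
      outer(x, slopes[idx])
    losses <- colSums(U * (tau - (U < 0)))
    j <- which.min(losses)
    if (losses[j] < best_loss - 1e-12) {
      best_loss <- losses[j]; best_i <- idx[j]
    }
  }
  tib <- tibble::tibble(tau = as.character(tau),
                        slope = slopes[best_i], intercept = intercepts[best_i],
                        p_value = NA_real_, n = n)
  attr(tib, "loss") <- best_loss
  tib
}
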