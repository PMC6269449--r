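#' Bundled reference summaries from a 23-site US Midwest soybean N trial
#'
#' Published per-site treatment means from a 2016 network of soybean
#' nitrogen-response trials across the US Midwest (23 sites, four N
#' treatments): seed yield (kg/ha at 13.5% moisture), seed protein and oil
#' (g/100 g dry basis) and RAU at R6 (%). These printed summaries are the
#' calibration anchor for the synthetic generator and the inputs for the
#' reproduction checks (site means, BNF grouping, derived curve traits).
#'
#' * `midwest_site_means()`: one row per site x treatment.
#' * `midwest_curve_params()`: the fitted beta-curve parameter table per
#'   BNF group x treatment -- `rau_max`, `t_m`, `t_max` with standard
#'   errors, the derived `t_half` and `max_rate`, and goodness of fit
#'   (`syx`, `r2`). The published AUC column cannot be recovered
#'   unambiguously from the typeset source and is stored as `NA`.
#'
#' @return A tibble.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
midwest_site_means <- function() {
  path <- system.file("extdata", "midwest_site_means.csv", package = "bnfcurve",
                      mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname reference_tables
#' @export
midwest_curve_params <- function() {
  path <- system.file("extdata", "midwest_curve_params.csv", package = "bnfcurve",
                      mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
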