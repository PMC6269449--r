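#' Relative abundance of ureides (RAU)
#'
#' Converts paired stem ureide and nitrate concentrations into the relative
#' abundance of ureides, the standard proxy for the fraction of plant
#' nitrogen derived from symbiotic fixation in ureide-exporting legumes:
#' \deqn{RAU (\%) = 100 \times \frac{4 U}{4 U + N}}
#' where `U` is the ureide concentration and `N` the nitrate concentration.
#' The factor 4 converts ureide molecules to nitrogen atoms (allantoin and
#' allantoic acid each carry four N). The ratio is unit-invariant, so any
#' single consistent concentration unit may be used for both inputs.
#'
#' @param ureide_conc Numeric vector of ureide concentrations (>= 0).
#' @param nitrate_conc Numeric vector of nitrate concentrations (>= 0), same
#'   unit basis as `ureide_conc`.
#' @return Numeric vector of RAU values in percent, in `[0, 100]`.
#' @examples
#' compute_rau(1, 4) # 4U = N, exactly 50
#' @export
compute_rau <- function(ureide_conc, nitrate_conc) {
  if (!is.numeric(ureide_conc) || !is.numeric(nitrate_conc)) {
    bnf_error("ureide and nitrate concentrations must be numeric", "bnf_domain_error")
  }
  n <- max(length(ureide_conc), length(nitrate_conc))
  u <- rep_len(as.numeric(ureide_conc), n)
  no3 <- rep_len(as.numeric(nitrate_conc), n)
  if (any(u < 0, na.rm = TRUE) || any(no3 < 0, na.rm = TRUE)) {
    bnf_error("negative concentration: RAU is defined for non-negative inputs only",
              "bnf_domain_error")
  }
  both_zero <- !is.na(u) & !is.na(no3) & u == 0 & no3 == 0
  if (any(both_zero)) {
    bnf_error("RAU undefined where ureide and nitrate are both zero",
              "bnf_undefined_rau_error")
  }
  100 * 4 * u / (4 * u + no3)
}

#' Cumulative thermal time over a date range
#'
#' Accumulates daily degree-days between `start` and `end` (both inclusive):
#' \deqn{TT = \sum \max\!\left(0,\; \frac{T_{max}+T_{min}}{2} - T_{base}\right)}
#' Daily increments below zero are clamped to zero (negative degree-day
#' accumulation is biologically meaningless); no upper temperature cutoff is
#' applied. The default base temperature is the conventional 8 degC for
#' soybean development.
#'
#' @param weather Data frame with columns `date` (Date or ISO-8601 string),
#'   `tmax_c` and `tmin_c` (daily maximum/minimum air temperature, degC).
#' @param base_temp Base temperature in degC (default 8).
#' @param start,end First and last day to accumulate (inclusive). Default to
#'   the range of `weather`.
#' @return Cumulative thermal time in degC-days (degCd), a non-negative scalar.
#' @seealso [thermal_clock()] for stage-anchored cumulative series.
#' @export
accumulate_thermal_time <- function(weather, base_temp = 8, start = NULL, end = NULL) {
  w <- validate_weather(weather)
  if (is.null(start)) start <- min(w$date)
  if (is.null(end)) end <- max(w$date)
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) return(0)
  wanted <- seq(start, end, by = "day")
  idx <- match(wanted, w$date)
  if (anyNA(idx)) {
    missing_days <- wanted[is.na(idx)]
    bnf_error(sprintf("weather has gaps in [%s, %s]: missing %s",
                      start, end, paste(missing_days, collapse = ", ")),
              "bnf_weather_gap_error")
  }
  inc <- pmax(0, (w$tmax_c[idx] + w$tmin_c[idx]) / 2 - base_temp)
  sum(inc)
}

#' Thermal clock anchored at a crop-stage date
#'
#' Builds the cumulative thermal-time series used as the developmental time
#' axis of the analysis, with the origin at a stage anchor (V2 for the
#' seasonal RAU work). Cumulative thermal time is 0 at the origin date and
#' accrues daily thereafter, so stage dates can be mapped to degCd with
#' [stage_thermal_times()].
#'
#' @param weather Weather data frame as in [accumulate_thermal_time()].
#' @param origin_date Anchor date (thermal time 0), typically the V2 stage.
#' @param base_temp Base temperature in degC (default 8).
#' @return An object of class `thermal_clock`: list with `origin_date`,
#'   `base_temp`, and a data frame `cumulative` (`date`, `tt`).
#' @export
thermal_clock <- function(weather, origin_date, base_temp = 8) {
  w <- validate_weather(weather)
  origin_date <- as.Date(origin_date)
  if (!origin_date %in% w$date) {
    bnf_error("origin_date is not covered by the weather record", "bnf_weather_gap_error")
  }
  after <- w[w$date >= origin_date, , drop = FALSE]
  all_days <- seq(origin_date, max(after$date), by = "day")
  if (!all(all_days %in% after$date)) {
    bnf_error("weather has gaps after origin_date", "bnf_weather_gap_error")
  }
  after <- after[order(after$date), , drop = FALSE]
  inc <- pmax(0, (after$tmax_c + after$tmin_c) / 2 - base_temp)
  inc[1] <- 0 # the origin day itself carries no accumulation
  structure(
    list(origin_date = origin_date, base_temp = base_temp,
         cumulative = data.frame(date = after$date, tt = cumsum(inc))),
    class = "thermal_clock"
  )
}

#' Map phenological-stage dates to thermal time
#'
#' Looks each stage date up on a [thermal_clock()], returning the cumulative
#' degC-days from the clock origin. Stage dates must not precede the origin,
#' and the result is non-decreasing in calendar order.
#'
#' @param clock A `thermal_clock`.
#' @param stage_dates Named vector or list of dates, e.g.
#'   `c(V4 = "2016-06-20", R2 = "2016-07-10", ...)`.
#' @return Named numeric vector of thermal times (degCd), one per stage.
#' @export
stage_thermal_times <- function(clock, stage_dates) {
  stopifnot(inherits(clock, "thermal_clock"))
  dates <- as.Date(unlist(lapply(stage_dates, as.character)))
  names(dates) <- names(stage_dates)
  if (is.null(names(dates)) || any(!nzchar(names(dates)))) {
    bnf_error("stage_dates must be named by stage", "bnf_domain_error")
  }
  if (any(dates < clock$origin_date)) {
    bad <- names(dates)[dates < clock$origin_date]
    bnf_error(sprintf("stage date(s) before the clock origin: %s",
                      paste(bad, collapse = ", ")), "bnf_stage_order_error")
  }
  idx <- match(dates, clock$cumulative$date)
  if (anyNA(idx)) {
    bnf_error("stage date(s) beyond the weather record", "bnf_weather_gap_error")
  }
  setNames(clock$cumulative$tt[idx], names(dates))
}

# --- internal validation -----------------------------------------------------

validate_weather <- function(weather) {
  req <- c("date", "tmax_c", "tmin_c")
  if (!is.data.frame(weather) || !all(req %in% names(weather))) {
    bnf_error("weather must be a data frame with columns date, tmax_c, tmin_c",
              "bnf_schema_error")
  }
  w <- as.data.frame(weather)[req]
  w$date <- as.Date(w$date)
  if (anyNA(w$date)) bnf_error("weather dates failed to parse", "bnf_schema_error")
  if (any(w$tmax_c < w$tmin_c, na.rm = TRUE)) {
    bnf_error("tmax_c < tmin_c in weather record", "bnf_schema_error")
  }
  w[order(w$date), , drop = FALSE]
}

#' @rdname readers
#' @export
treatment_levels <- function() c("control", "N_sowing", "N_V4", "N_R2")

#' @rdname readers
#' @export
stage_levels <- function() c("V4", "R2", "R6", "R8")

#' Readers for assay, weather and trial tables
#'
#' Strict CSV readers for the pipeline's external interfaces. Unknown
#' treatment or stage labels are rejected with the offending line numbers
#' (header is line 1). All readers return tibbles.
#'
#' * `read_weather_csv()`: columns `date` (ISO-8601), `tmax_c`, `tmin_c`,
#'   optionally `site_id`.
#' * `read_assay_csv()`: columns `site_id`, `treatment`, `block`, `stage`,
#'   `ureide_conc`, `nitrate_conc`.
#' * `read_trial_csv()`: columns `site_id`, `treatment`, `block`, `tt_r6`,
#'   `rau_r6`, `seed_yield`, `biomass`, `hi`, `protein`, `oil`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with validated columns.
#' @name readers
NULL

#' @rdname readers
#' @export
read_weather_csv <- function(path) {
  w <- read.csv(path, stringsAsFactors = FALSE)
  validate_weather(w)
  tibble::as_tibble(w)
}

#' @rdname readers
#' @export
read_assay_csv <- function(path) {
  a <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "treatment", "block", "stage", "ureide_conc", "nitrate_conc")
  miss <- setdiff(req, names(a))
  if (length(miss)) {
    bnf_error(sprintf("assay CSV missing column(s): %s", paste(miss, collapse = ", ")),
              "bnf_schema_error")
  }
  check_labels(a$treatment, treatment_levels(), "treatment", path)
  check_labels(a$stage, stage_levels(), "stage", path)
  if (any(a$ureide_conc < 0 | a$nitrate_conc < 0, na.rm = TRUE)) {
    bnf_error("negative concentrations in assay CSV", "bnf_domain_error")
  }
  tibble::as_tibble(a)
}

#' @rdname readers
#' @export
read_trial_csv <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "treatment", "block", "tt_r6", "rau_r6",
           "seed_yield", "biomass", "hi", "protein", "oil")
  miss <- setdiff(req, names(tr))
  if (length(miss)) {
    bnf_error(sprintf("trial CSV missing column(s): %s", paste(miss, collapse = ", ")),
              "bnf_schema_error")
  }
  check_labels(tr$treatment, treatment_levels(), "treatment", path)
  bad_hi <- !is.na(tr$hi) & (tr$hi <= 0 | tr$hi >= 1)
  if (any(bad_hi)) {
    bnf_error(sprintf("harvest index outside (0,1) at line(s) %s of %s",
                      paste(which(bad_hi) + 1L, collapse = ", "), path),
              "bnf_schema_error")
  }
  bad_rau <- !is.na(tr$rau_r6) & (tr$rau_r6 < 0 | tr$rau_r6 > 100)
  if (any(bad_rau)) {
    bnf_error(sprintf("rau_r6 outside [0,100] at line(s) %s of %s",
                      paste(which(bad_rau) + 1L, collapse = ", "), path),
              "bnf_schema_error")
  }
  tibble::as_tibble(tr)
}

check_labels <- function(x, allowed, what, path) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (any(bad)) {
    lines <- which(bad) + 1L # header occupies line 1
    bnf_error(sprintf("unknown %s label(s) %s at line(s) %s of %s (allowed: %s)",
                      what, paste(unique(x[bad]), collapse = ", "),
                      paste(head(lines, 10), collapse = ", "), path,
                      paste(allowed, collapse = ", ")),
              "bnf_label_error")
  }
  invisible(TRUE)
}
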