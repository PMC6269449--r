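#' Specification for a synthetic multi-environment soybean N trial
#'
#' Defines the study conditions the generator emulates: a 23-site network
#' across a wide latitude (hence maturity-group / season-length) range,
#' four nitrogen treatments (unfertilised control and 112 kg N/ha at
#' sowing, V4 or R2) in three complete blocks, stem ureide assays at
#' V4/R2/R6/R8, and agronomic outcomes at maturity.
#'
#' Defaults are calibrated to the observed study conditions:
#' * Group base curves (control): high (90, 397, 1117), medium
#'   (84, 362, 1066), low (71, 0, 931) for (rau_max, t_m, t_max).
#' * Treatment effects: additive shifts on the triple, applied uniformly
#'   across groups; defaults are the high-group control-vs-treatment
#'   contrasts (N at R2: -15% on rau_max, the strongest peak reduction).
#' * Plot-level RAU noise SD 13% (the middle of the observed 11-16% Syx
#'   band).
#' * Thermal time to R6 uniform on [909, 1733] degCd; assay stages at
#'   phases 0.15 (V4), 0.48 (R2), 1 (R6), 1.5 (R8) of tt_r6; site curves
#'   scale t_m and t_max with season length as
#'   `(tt_r6 / 1150)^scale_exponent` (default exponent 1, i.e. fully
#'   proportional). Full scaling makes every site's trajectory
#'   phase-consistent, so RAU at R6 is independent of season length within
#'   a group -- the configuration under which the de-trending step can
#'   recover an injected BNF cost without confounding. Its price is that
#'   pooled fits across a wide season range carry extra between-site
#'   dispersion on the absolute thermal-time axis; analyses that target
#'   the published per-group curve conditions use a common season
#'   (`tt_r6_range = c(1150, 1150)`), where the refit residual SD equals
#'   the plot noise.
#' * Yield/HI/oil: continuous bilinear phenology trend plus a linear BNF
#'   cost in RAU_R6 (yield -13 kg/ha per %, HI -0.0011 per %, oil -0.03
#'   g/100g per %) plus Gaussian noise. Biomass is derived as yield/HI so
#'   the two cost terms approximately cancel (biomass carries no net BNF
#'   signal), and protein carries none by construction.
#'
#' @param n_sites Number of sites (default 23).
#' @param treatments Treatment labels (default [treatment_levels()]).
#' @param n_blocks Blocks per site (default 3).
#' @param group_params Named list group -> c(rau_max, t_m, t_max).
#' @param treatment_effects Named list treatment -> additive shift triple.
#' @param rau_noise_sd RAU residual SD in percent.
#' @param tt_r6_range Range for per-site thermal time to R6 (degCd).
#' @param stage_phases Named vector of stage thermal times as fractions of
#'   tt_r6.
#' @param ref_tt_r6 Reference season length for curve scaling (degCd).
#' @param scale_exponent Exponent of the season-length scaling of `t_m`
#'   and `t_max` (0 = identical curves at all sites, 1 = fully
#'   proportional).
#' @param yield_model,hi_model,oil_model,protein_model Lists with bilinear
#'   parameters `a`, `b`, `d`, `tt_o`, BNF cost `bnf_cost_slope` (per %
#'   RAU_R6) and `noise_sd`.
#' @param heteroscedastic If `TRUE`, trait noise SD scales with distance
#'   below the phenology trend, producing the widening lower boundary that
#'   extreme-quantile regression is designed to capture.
#' @param seed Integer seed; every draw in [simulate_trials()] derives
#'   from it.
#' @return A list of class `bnf_sim_spec`.
#' @export
simulation_spec <- function(
    n_sites = 23,
    treatments = treatment_levels(),
    n_blocks = 3,
    group_params = list(high = c(rau_max = 90, t_m = 397, t_max = 1117),
                        medium = c(rau_max = 84, t_m = 362, t_max = 1066),
                        low = c(rau_max = 71, t_m = 0, t_max = 931)),
    treatment_effects = list(control = c(0, 0, 0),
                             N_sowing = c(-7, 64, 36),
                             N_V4 = c(-9, -9, -14),
                             N_R2 = c(-15, -140, -45)),
    rau_noise_sd = 13,
    tt_r6_range = c(909, 1733),
    stage_phases = c(V4 = 0.15, R2 = 0.48, R6 = 1, R8 = 1.5),
    ref_tt_r6 = 1150,
    scale_exponent = 1,
    yield_model = list(a = 4.5, b = -800, d = 2.0, tt_o = 1300,
                       bnf_cost_slope = -13, noise_sd = 250),
    hi_model = list(a = -2e-5, b = 0.52, d = -8e-5, tt_o = 1300,
                    bnf_cost_slope = -0.0011, noise_sd = 0.015),
    oil_model = list(a = 0.002, b = 18.5, d = 0.004, tt_o = 1300,
                     bnf_cost_slope = -0.03, noise_sd = 0.8),
    protein_model = list(a = -0.002, b = 40, d = -0.002, tt_o = 1300,
                         bnf_cost_slope = 0, noise_sd = 1.2),
    heteroscedastic = FALSE,
    seed = 1L) {
  if (rau_noise_sd < 0) bnf_error("rau_noise_sd must be >= 0", "bnf_spec_error")
  if (any(diff(stage_phases[order(stage_phases)]) <= 0) ||
      is.unsorted(stage_phases)) {
    bnf_error("stage_phases must be strictly increasing", "bnf_spec_error")
  }
  for (g in names(group_params)) {
    p <- group_params[[g]]
    if (p[2] >= p[3] || p[1] <= 0 || p[1] > 100 || p[2] < 0) {
      bnf_error(sprintf("group %s parameters violate beta-curve invariants", g),
                "bnf_spec_error")
    }
  }
  for (m in list(yield_model, hi_model, oil_model, protein_model)) {
    if (m$noise_sd < 0) bnf_error("trait noise SDs must be >= 0", "bnf_spec_error")
  }
  structure(as.list(environment()), class = "bnf_sim_spec")
}

# per-site curve triple for one treatment: time axis scaled with season
# length, clamped to valid parameter space
site_curve_params <- function(spec, group, treatment, tt_r6) {
  base <- spec$group_params[[group]]
  shift <- spec$treatment_effects[[treatment]]
  if (is.null(shift)) shift <- c(0, 0, 0)
  s <- (tt_r6 / spec$ref_tt_r6)^spec$scale_exponent
  rau_max <- min(max(base[1] + shift[1], 1), 100)
  t_m <- max(base[2] + shift[2], 0) * s
  t_max <- (base[3] + shift[3]) * s
  if (t_m >= t_max) t_m <- 0.95 * t_max
  c(rau_max = unname(rau_max), t_m = unname(t_m), t_max = unname(t_max))
}

#' Simulate one stem ureide assay
#'
#' Draws the true RAU from the site/treatment beta curve at the stage's
#' thermal time, adds Gaussian noise (clipped to `[0, 100]`), and emits a
#' (ureide, nitrate) concentration pair that inverts the RAU formula
#' exactly: ureide fixed at 1 and `nitrate = 4(100 - RAU)/RAU`, so
#' [compute_rau()] recovers the simulated RAU to machine precision. A
#' simulated RAU of 0 is emitted as (ureide 0, nitrate 1).
#'
#' @param spec A [simulation_spec()].
#' @param site Site index (used only for labelling).
#' @param group BNF group of the site.
#' @param treatment Treatment label.
#' @param stage Stage label (must be in `names(spec$stage_phases)`).
#' @param tt_r6 The site's thermal time to R6 (degCd).
#' @return One-row tibble: `site_id`, `treatment`, `stage`, `ureide_conc`,
#'   `nitrate_conc`, `rau_true` (the noisy clipped value the pair encodes).
#' @export
simulate_rau <- function(spec, site, group, treatment, stage, tt_r6) {
  stopifnot(inherits(spec, "bnf_sim_spec"))
  if (!stage %in% names(spec$stage_phases)) {
    bnf_error(sprintf("unknown stage %s", stage), "bnf_label_error")
  }
  p <- site_curve_params(spec, group, treatment, tt_r6)
  tt <- spec$stage_phases[[stage]] * tt_r6
  mu <- beta_rau(tt, p[["rau_max"]], p[["t_m"]], p[["t_max"]])
  rau <- min(max(mu + rnorm(1, 0, spec$rau_noise_sd), 0), 100)
  if (rau == 0) {
    u <- 0; no3 <- 1
  } else {
    u <- 1; no3 <- 4 * (100 - rau) / rau
  }
  tibble::tibble(site_id = sprintf("site_%02d", site), treatment = treatment,
                 stage = stage, ureide_conc = u, nitrate_conc = no3,
                 rau_true = rau)
}

#' Simulate a complete multi-site trial
#'
#' Generates, deterministically from `spec$seed`, the full data bundle the
#' pipeline consumes:
#' * `assays`: one stem assay per site x treatment x block x stage, as
#'   (ureide, nitrate) pairs.
#' * `weather` and `stage_dates`: per-site daily weather constructed so
#'   that [accumulate_thermal_time()] from the V2 anchor reproduces each
#'   stage's target thermal time exactly (constant daily mean within each
#'   stage interval, diurnal range 12 degC).
#' * `trials`: per-plot agronomic outcomes. Seed yield, HI and oil follow
#'   their bilinear phenology trend in tt_r6 plus the configured linear
#'   BNF cost in (rau_r6 - mean rau_r6) plus noise; biomass = yield / HI;
#'   protein carries no BNF signal.
#' * `observations`: assays joined with stage thermal times and RAU, ready
#'   for [pooled_group_curves()].
#' * `truth`: the per-site group allocation, season lengths and curve
#'   parameters actually used.
#'
#' Sites are allocated to low/medium/high groups in quartile proportions
#' (floor(n/4) low, round(n/4) high, rest medium -- 5/12/6 at n = 23) by a
#' seeded permutation, independent of season length.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Optional directory: write `assays.csv`, `weather.csv`,
#'   `stage_dates.csv`, `trials.csv`.
#' @return List with `assays`, `weather`, `stage_dates`, `trials`,
#'   `observations`, `truth`.
#' @export
simulate_trials <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "bnf_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_sites
  n_low <- floor(n / 4); n_high <- round(n / 4)
  n_med <- n - n_low - n_high
  if (n_med < 1) bnf_error("too few sites to form three groups", "bnf_spec_error")
  group_alloc <- sample(c(rep("low", n_low), rep("medium", n_med), rep("high", n_high)))
  tt_r6 <- runif(n, spec$tt_r6_range[1], spec$tt_r6_range[2])

  site_ids <- sprintf("site_%02d", seq_len(n))
  truth <- tibble::tibble(site_id = site_ids, group = group_alloc, tt_r6 = tt_r6)

  # --- assays + observations -------------------------------------------------
  obs_rows <- vector("list", n * length(spec$treatments) * spec$n_blocks *
                       length(spec$stage_phases))
  k <- 0L
  for (i in seq_len(n)) {
    for (tr in spec$treatments) {
      p <- site_curve_params(spec, group_alloc[i], tr, tt_r6[i])
      for (b in seq_len(spec$n_blocks)) {
        for (st in names(spec$stage_phases)) {
          tt <- spec$stage_phases[[st]] * tt_r6[i]
          mu <- beta_rau(tt, p[["rau_max"]], p[["t_m"]], p[["t_max"]])
          rau <- min(max(mu + rnorm(1, 0, spec$rau_noise_sd), 0), 100)
          k <- k + 1L
          obs_rows[[k]] <- data.frame(
            site_id = site_ids[i], treatment = tr, block = b, stage = st,
            t = tt, rau = rau, stringsAsFactors = FALSE)
        }
      }
    }
  }
  observations <- tibble::as_tibble(do.call(rbind, obs_rows))
  observations$ureide_conc <- ifelse(observations$rau == 0, 0, 1)
  observations$nitrate_conc <- ifelse(observations$rau == 0, 1,
                                      4 * (100 - observations$rau) / observations$rau)
  assays <- observations[c("site_id", "treatment", "block", "stage",
                           "ureide_conc", "nitrate_conc")]

  # --- weather reproducing the stage thermal times ---------------------------
  weather_rows <- list(); stage_rows <- list()
  for (i in seq_len(n)) {
    stage_tts <- spec$stage_phases * tt_r6[i]
    origin <- as.Date("2016-05-20") + (i - 1L) %% 7L # staggered sowing weeks
    bounds <- c(0, stage_tts)
    dates <- origin; incs <- 0 # origin day, no accumulation
    for (j in seq_along(stage_tts)) {
      delta <- bounds[j + 1] - bounds[j]
      nd <- max(1L, ceiling(delta / 15))
      incs <- c(incs, rep(delta / nd, nd))
    }
    all_dates <- seq(origin, by = "day", length.out = length(incs) + 10L)
    incs <- c(incs, rep(12, 10L)) # tail days past R8
    mean_t <- 8 + incs
    weather_rows[[i]] <- data.frame(
      site_id = site_ids[i], date = all_dates,
      tmax_c = mean_t + 6, tmin_c = mean_t - 6, stringsAsFactors = FALSE)
    cum <- cumsum(incs)
    stage_dates <- vapply(stage_tts, function(ttv) {
      as.character(all_dates[which(cum >= ttv - 1e-9)[1]])
    }, character(1))
    stage_rows[[i]] <- data.frame(
      site_id = site_ids[i],
      stage = c("V2", names(spec$stage_phases)),
      date = c(as.character(origin), stage_dates), stringsAsFactors = FALSE)
  }
  weather <- tibble::as_tibble(do.call(rbind, weather_rows))
  stage_dates <- tibble::as_tibble(do.call(rbind, stage_rows))

  # --- agronomic outcomes ----------------------------------------------------
  r6 <- observations[observations$stage == "R6",
                     c("site_id", "treatment", "block", "rau")]
  names(r6)[names(r6) == "rau"] <- "rau_r6"
  mean_rau <- mean(r6$rau_r6)
  trend <- function(m, x) {
    ifelse(x < m$tt_o, m$a * x + m$b, m$a * m$tt_o + m$b + m$d * (x - m$tt_o))
  }
  trials <- r6
  trials$tt_r6 <- tt_r6[match(trials$site_id, site_ids)]
  npl <- nrow(trials)
  dev <- trials$rau_r6 - mean_rau
  noise_scale <- if (spec$heteroscedastic) {
    1 + 1.5 * pmax(0, dev) / max(1, max(abs(dev))) # noisier below the boundary at high RAU
  } else rep(1, npl)
  trials$seed_yield <- trend(spec$yield_model, trials$tt_r6) +
    spec$yield_model$bnf_cost_slope * dev +
    rnorm(npl, 0, spec$yield_model$noise_sd) * noise_scale
  trials$hi <- pmin(0.65, pmax(0.2,
    trend(spec$hi_model, trials$tt_r6) + spec$hi_model$bnf_cost_slope * dev +
      rnorm(npl, 0, spec$hi_model$noise_sd) * noise_scale))
  trials$oil <- trend(spec$oil_model, trials$tt_r6) +
    spec$oil_model$bnf_cost_slope * dev + rnorm(npl, 0, spec$oil_model$noise_sd)
  trials$protein <- trend(spec$protein_model, trials$tt_r6) +
    spec$protein_model$bnf_cost_slope * dev + rnorm(npl, 0, spec$protein_model$noise_sd)
  trials$biomass <- trials$seed_yield / trials$hi
  trials <- tibble::as_tibble(trials[c("site_id", "treatment", "block", "tt_r6",
                                       "rau_r6", "seed_yield", "biomass", "hi",
                                       "protein", "oil")])

  out <- list(assays = tibble::as_tibble(assays), weather = weather,
              stage_dates = stage_dates, trials = trials,
              observations = observations, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("assays", "weather", "stage_dates", "trials")) {
      write.csv(as.data.frame(out[[nm]]), file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  out
}
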