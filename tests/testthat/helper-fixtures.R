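# constant-temperature weather: daily mean = base + inc, so each day accrues
# exactly `inc` degree-days above an 8 degC base
flat_weather <- function(start, n_days, inc = 17, base = 8) {
  mean_t <- base + inc
  data.frame(date = seq(as.Date(start), by = "day", length.out = n_days),
             tmax_c = mean_t + 6, tmin_c = mean_t - 6)
}

# stage thermal times for a network of sites sharing one true curve:
# 4 stages at fixed phases of each site's season
stage_grid <- function(site_seasons, phases = c(0.15, 0.48, 1, 1.5)) {
  as.vector(outer(phases, site_seasons))
}

# the 23 printed control RAU_R6 values (named by site), from the bundled
# reference table
control_rau_reference <- function() {
  sm <- midwest_site_means()
  ctrl <- sm[sm$treatment == "control", ]
  setNames(ctrl$rau_r6, ctrl$site_id)
}
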