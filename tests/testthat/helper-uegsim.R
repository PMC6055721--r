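# shared fixtures, built in code

# a smooth 240-site activation/repolarization field at a given cycle length
make_field <- function(seed = 1, cl = 600, n_sites = 240,
                       rt_dispersion_max = NULL) {
  cfg <- generator_config(cycle_length = cl, n_sites = n_sites)
  geo <- gen_geometry(cfg, seed = seed)
  gen_timing_fields(geo, cfg, seed = seed,
                    rt_dispersion_max = rt_dispersion_max)
}

# a marker_map carrying ground-truth times (all valid)
truth_markers <- function(truth) {
  mk <- data.frame(site_id = truth$site_id,
                   AT_ms = truth$tau_AT, RT_ms = truth$tau_RT,
                   ARI_ms = truth$tau_RT - truth$tau_AT,
                   valid = TRUE, reason = "", stringsAsFactors = FALSE)
  class(mk) <- c("marker_map", "data.frame")
  mk
}

# snap timing columns to a 1 kHz lattice (markers measured on sampled
# recordings are integer ms)
snap_ms <- function(truth) {
  truth$tau_AT <- round(truth$tau_AT)
  truth$tau_RT <- round(truth$tau_RT)
  truth
}

# recorded-vs-model round trip as the validation pipeline performs it:
# measure markers on a "recorded" matrix, inform the model with them,
# re-measure on the simulated UEGs
two_stage_round_trip <- function(truth, cl) {
  r1 <- suppressWarnings(marker_round_trip(truth, cl))
  ok <- r1$markers$valid
  inform <- data.frame(tau_AT = r1$markers$AT_ms[ok],
                       tau_RT = r1$markers$RT_ms[ok])
  r2 <- suppressWarnings(marker_round_trip(inform, cl))
  ok2 <- r2$markers$valid
  list(stage1 = r1, stage2 = r2, inform = inform,
       dAT = r2$markers$AT_ms[ok2] - inform$tau_AT[ok2],
       dRT = r2$markers$RT_ms[ok2] - inform$tau_RT[ok2],
       cc_at = r2$cc_at, cc_rt = r2$cc_rt)
}
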