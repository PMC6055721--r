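#' Run the full validation pipeline on one dataset
#'
#' End-to-end analysis of one paced acquisition at one cycle length:
#' segment beats, QC (beat stability then spectral SNR), signal averaging,
#' automatic QRS/T-wave windowing, marker detection, steepness grid search,
#' UEG simulation from the measured markers, re-measurement of markers on
#' the simulated UEGs, and morphology/timing-area statistics.  The result
#' mirrors the per-cycle-length rows of a recorded-vs-model comparison
#' table.
#'
#' @param dataset a `sock_dataset` from [synthetic_sock()], or any list
#'   with `raw` (a [signal_matrix()]), `stim_times` and a `config` holding
#'   `cycle_length` (ms); an optional `truth` marker data.frame adds
#'   ground-truth columns to the summary.
#' @param qc a [qc_config()].
#' @param grid a [beta_grid()]; a single-pair grid effectively fixes beta.
#' @param scaling a [conductivity_scaling()] or bare alpha.
#' @param artifact_ms post-stimulus blanking used for windowing,
#'   correlations and the grid search.
#' @param out_dir optional output directory; when given, writes
#'   `qc_report.csv`, `markers.csv`, `beta_scores.csv`, `morphology.csv`
#'   and `summary.json`.
#' @return An object of class `validation_summary`: list with `summary`
#'   (named numerics), `qc_report`, `markers_recorded`, `markers_simulated`,
#'   `beta`, `morphology`, `windows`, `n_sites`.
#' @export
run_validation <- function(dataset, qc = qc_config(), grid = beta_grid(),
                           scaling = conductivity_scaling(),
                           artifact_ms = 10, out_dir = NULL) {
  cl <- dataset$config$cycle_length
  stack <- segment_beats(dataset$raw, dataset$stim_times, cl,
                         n_discard = qc$n_discard_initial_beats)
  qcres <- qc_filter(stack, qc)
  kept <- qcres$report$kept
  if (!any(kept)) stop("QC stage left zero sites")
  avg <- signal_matrix(qcres$averaged$samples[kept, , drop = FALSE],
                       fs = qcres$averaged$fs, t0 = qcres$averaged$t0,
                       site_id = qcres$averaged$site_id[kept])
  windows <- auto_windows(avg, artifact_ms = artifact_ms)
  markers_rec <- mark_all(avg, windows)
  if (!any(markers_rec$valid)) stop("marker stage left zero valid sites")

  search <- grid_search_beta(avg, markers_rec, grid, scaling,
                             artifact_ms = artifact_ms)
  ok <- markers_rec$valid
  params <- ap_params(beta_AT = search$beta_AT, beta_RT = search$beta_RT)
  sim <- simulate_ueg(
    ap_ensemble(time_axis(avg), params,
                data.frame(site_id = markers_rec$site_id[ok],
                           tau_AT = markers_rec$AT_ms[ok],
                           tau_RT = markers_rec$RT_ms[ok])),
    scaling)
  avg_ok <- signal_matrix(avg$samples[ok, , drop = FALSE], fs = avg$fs,
                          t0 = avg$t0, site_id = avg$site_id[ok])
  markers_sim <- mark_all(sim, windows)
  morph <- morphology_compare(avg_ok, sim, windows, artifact_ms = artifact_ms)
  rec_ok <- markers_rec[ok, ]

  tam_rec <- timing_area_maps(rec_ok, morph$per_site$qrs_area_rec,
                              morph$per_site$twave_area_rec)
  tam_sim <- timing_area_maps(markers_sim, morph$per_site$qrs_area_sim,
                              morph$per_site$twave_area_sim)

  both <- rec_ok$valid & markers_sim$valid
  dAT <- rec_ok$AT_ms[both] - markers_sim$AT_ms[both]
  dRT <- rec_ok$RT_ms[both] - markers_sim$RT_ms[both]
  dARI <- rec_ok$ARI_ms[both] - markers_sim$ARI_ms[both]
  madm <- function(v) stats::median(abs(v - stats::median(v)))

  summary <- list(
    cycle_length = cl,
    n_sites_input = length(kept),
    n_sites_qc = sum(kept),
    n_sites_valid = sum(both),
    beta_AT = search$beta_AT, beta_RT = search$beta_RT,
    delta_at_median = stats::median(dAT), delta_at_mad = madm(dAT),
    delta_rt_median = stats::median(dRT), delta_rt_mad = madm(dRT),
    delta_ari_median = stats::median(dARI), delta_ari_mad = madm(dARI),
    cc_at = pearson_cc(rec_ok$AT_ms[both], markers_sim$AT_ms[both])$cc,
    cc_rt = pearson_cc(rec_ok$RT_ms[both], markers_sim$RT_ms[both])$cc,
    cc_ari = pearson_cc(rec_ok$ARI_ms[both], markers_sim$ARI_ms[both])$cc,
    cc_whole_median = stats::median(morph$per_site$cc_whole, na.rm = TRUE),
    cc_qrs_median = stats::median(morph$per_site$cc_qrs, na.rm = TRUE),
    cc_twave_median = stats::median(morph$per_site$cc_twave, na.rm = TRUE),
    cc_qrsa = pearson_cc(morph$per_site$qrs_area_rec,
                         morph$per_site$qrs_area_sim)$cc,
    cc_twa = pearson_cc(morph$per_site$twave_area_rec,
                        morph$per_site$twave_area_sim)$cc,
    cc_at_qrsa_rec = tam_rec$cc_at_qrsa, cc_rt_twa_rec = tam_rec$cc_rt_twa,
    cc_at_qrsa_sim = tam_sim$cc_at_qrsa, cc_rt_twa_sim = tam_sim$cc_rt_twa)

  if (!is.null(dataset$truth)) {
    tr <- dataset$truth[match(rec_ok$site_id[both], dataset$truth$site_id), ]
    summary$delta_at_truth_median <-
      stats::median(rec_ok$AT_ms[both] - tr$tau_AT)
    summary$delta_rt_truth_median <-
      stats::median(rec_ok$RT_ms[both] - tr$tau_RT)
    summary$cc_at_truth <- pearson_cc(rec_ok$AT_ms[both], tr$tau_AT)$cc
    summary$cc_rt_truth <- pearson_cc(rec_ok$RT_ms[both], tr$tau_RT)$cc
  }

  res <- structure(list(summary = summary, qc_report = qcres$report,
                        markers_recorded = markers_rec,
                        markers_simulated = markers_sim,
                        beta = search, morphology = morph,
                        windows = windows, n_sites = sum(both)),
                   class = "validation_summary")
  if (!is.null(out_dir)) write_validation(res, out_dir)
  res
}

#' @export
print.validation_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("validation_summary (CL %g ms): %d/%d sites kept\n",
              s$cycle_length, s$n_sites_qc, s$n_sites_input))
  cat(sprintf("  beta = (%.3g, %.3g), median cc: whole %.3f qrs %.3f tw %.3f\n",
              s$beta_AT, s$beta_RT, s$cc_whole_median, s$cc_qrs_median,
              s$cc_twave_median))
  cat(sprintf("  dAT %g ms (cc %.4f), dRT %g ms (cc %.4f)\n",
              s$delta_at_median, s$cc_at, s$delta_rt_median, s$cc_rt))
  cat(sprintf("  cc(AT,QRSa) R/M %.3f/%.3f, cc(RT,TWa) R/M %.3f/%.3f\n",
              s$cc_at_qrsa_rec, s$cc_at_qrsa_sim,
              s$cc_rt_twa_rec, s$cc_rt_twa_sim))
  invisible(x)
}

#' Write the pipeline products of a validation run
#'
#' @param res a `validation_summary` from [run_validation()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_validation <- function(res, dir) {
  stopifnot(inherits(res, "validation_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$qc_report, file.path(dir, "qc_report.csv"),
                   row.names = FALSE)
  write_marker_map(res$markers_recorded, file.path(dir, "markers.csv"))
  utils::write.csv(res$beta$scores, file.path(dir, "beta_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(res$morphology$per_site, file.path(dir, "morphology.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Marker round-trip on model-simulated electrograms
#'
#' The core validation-by-design experiment: take per-site activation and
#' repolarization times, simulate UEGs with the forward model, re-measure
#' AT (steepest negative derivative in the QRS window) and RT (Wyatt
#' method) from the simulated signals, and compare against the input
#' times.  Timing inputs are snapped to the sampling lattice first, as
#' markers measured on sampled recordings would be.
#'
#' @param timings data.frame with `tau_AT`, `tau_RT` (ms).
#' @param cycle_length beat window in ms.
#' @param params an [ap_params()].
#' @param scaling a [conductivity_scaling()] or bare alpha.
#' @param fs sampling frequency (Hz).
#' @param snap snap timing inputs to the sampling lattice (default TRUE).
#' @return list with `truth` (snapped timings), `markers` (marker map from
#'   the simulated UEGs), `ueg` (the [signal_matrix()]), `windows`, and
#'   summary fields `delta_at_median`, `delta_rt_median`, `cc_at`, `cc_rt`.
#' @export
marker_round_trip <- function(timings, cycle_length, params = ap_params(),
                              scaling = conductivity_scaling(), fs = 1000,
                              snap = TRUE) {
  dt <- 1000 / fs
  timings <- as.data.frame(timings)
  if (snap) {
    timings$tau_AT <- round(timings$tau_AT / dt) * dt
    timings$tau_RT <- round(timings$tau_RT / dt) * dt
  }
  ueg <- ueg_from_timings(timings, cycle_length, params, scaling, fs)
  windows <- auto_windows(ueg, artifact_ms = 0)
  markers <- mark_all(ueg, windows)
  ok <- markers$valid
  dAT <- markers$AT_ms[ok] - timings$tau_AT[ok]
  dRT <- markers$RT_ms[ok] - timings$tau_RT[ok]
  list(truth = timings, markers = markers, ueg = ueg, windows = windows,
       delta_at_median = stats::median(dAT),
       delta_rt_median = stats::median(dRT),
       cc_at = pearson_cc(timings$tau_AT[ok], markers$AT_ms[ok])$cc,
       cc_rt = pearson_cc(timings$tau_RT[ok], markers$RT_ms[ok])$cc)
}
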