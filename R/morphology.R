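#' Pearson correlation with degenerate-input flagging
#'
#' Thin wrapper around [stats::cor()] that flags zero-variance inputs
#' instead of returning NA silently.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `cc` (NA if undefined) and `valid`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(cc = NA_real_, valid = FALSE))
  list(cc = stats::cor(x, y), valid = TRUE)
}

#' Signed area of a trace over a window
#'
#' Trapezoidal integral of `(V - baseline)` over the window, in mV*ms.
#' Signed: a net-negative QS complex gives a negative area, a prominent
#' R wave a positive one.
#'
#' @param trace a [signal_trace()].
#' @param window `[start, end]` ms.
#' @param baseline isoelectric reference in mV (see [estimate_baseline()]).
#' @return area in mV*ms.
#' @export
window_area <- function(trace, window, baseline = 0) {
  stopifnot(inherits(trace, "signal_trace"))
  idx <- window_idx(window, trace$fs, trace$t0, length(trace$samples))
  t <- time_axis(trace)[idx]
  pracma::trapz(t, trace$samples[idx] - baseline)
}

#' Isoelectric baseline of an averaged beat
#'
#' Median of the 20 ms immediately preceding the stimulus when pre-stimulus
#' samples exist (`t0 < 0`); otherwise the first sample of the beat, which
#' on stimulus-aligned beats precedes any deflection.
#'
#' @param trace a [signal_trace()].
#' @param pre_ms pre-stimulus span used for the median (ms).
#' @return baseline voltage in mV.
#' @export
estimate_baseline <- function(trace, pre_ms = 20) {
  stopifnot(inherits(trace, "signal_trace"))
  t <- time_axis(trace)
  pre <- t < 0 & t >= -pre_ms
  if (any(pre)) stats::median(trace$samples[pre]) else trace$samples[1]
}

#' Robust distribution summary
#'
#' Median, median absolute deviation (median of |X - median(X)|, no
#' consistency constant), quartiles (linear-interpolation type 7) and
#' Tukey outlier fences at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`.
#'
#' @param values numeric vector (NAs dropped).
#' @return list with `median`, `mad`, `q1`, `q3`, `fence_lo`, `fence_hi`,
#'   `n`, `n_outliers`.
#' @export
summarize_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to summarize")
  med <- stats::median(values)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fl <- q[1] - 1.5 * iqr
  fh <- q[2] + 1.5 * iqr
  list(median = med,
       mad = stats::median(abs(values - med)),
       q1 = q[1], q3 = q[2],
       fence_lo = fl, fence_hi = fh,
       n = length(values),
       n_outliers = sum(values < fl | values > fh))
}

#' Morphological comparison of two UEG matrices
#'
#' Per-site Pearson correlations between matched recorded and simulated
#' beats over (a) the entire beat excluding the first `artifact_ms` after
#' the stimulus, (b) the QRS window and (c) the T-wave window, plus signed
#' QRS and T-wave areas for both matrices and cohort summaries of every
#' metric.
#'
#' @param recorded,simulated [signal_matrix()] objects with matching site
#'   sets on the same grid.
#' @param windows a [beat_windows()].
#' @param artifact_ms post-stimulus span excluded from the whole-beat
#'   correlation (paced recordings carry a stimulus artifact the model does
#'   not produce).
#' @return A `morphology_report`: list with `per_site` (data.frame) and
#'   `summary` (named list of [summarize_stats()] results).
#' @export
morphology_compare <- function(recorded, simulated, windows,
                               artifact_ms = 10) {
  stopifnot(inherits(recorded, "signal_matrix"),
            inherits(simulated, "signal_matrix"),
            inherits(windows, "beat_windows"))
  if (nrow(recorded$samples) != nrow(simulated$samples) ||
      !all(recorded$site_id == simulated$site_id))
    stop("recorded and simulated site sets do not match")
  if (ncol(recorded$samples) != ncol(simulated$samples) ||
      recorded$fs != simulated$fs || recorded$t0 != simulated$t0)
    stop("recorded and simulated grids do not match")
  t <- time_axis(recorded)
  whole <- which(t >= artifact_ms)
  iq <- window_idx(windows$qrs, recorded$fs, recorded$t0, length(t))
  it <- window_idx(windows$twave, recorded$fs, recorded$t0, length(t))
  m <- nrow(recorded$samples)
  per <- data.frame(site_id = recorded$site_id,
                    cc_whole = NA_real_, cc_qrs = NA_real_,
                    cc_twave = NA_real_,
                    qrs_area_rec = NA_real_, twave_area_rec = NA_real_,
                    qrs_area_sim = NA_real_, twave_area_sim = NA_real_)
  for (i in seq_len(m)) {
    r <- recorded$samples[i, ]
    s <- simulated$samples[i, ]
    per$cc_whole[i] <- pearson_cc(r[whole], s[whole])$cc
    per$cc_qrs[i] <- pearson_cc(r[iq], s[iq])$cc
    per$cc_twave[i] <- pearson_cc(r[it], s[it])$cc
    tr <- get_trace(recorded, i)
    ts <- get_trace(simulated, i)
    br <- estimate_baseline(tr)
    bs <- estimate_baseline(ts)
    per$qrs_area_rec[i] <- window_area(tr, windows$qrs, br)
    per$twave_area_rec[i] <- window_area(tr, windows$twave, br)
    per$qrs_area_sim[i] <- window_area(ts, windows$qrs, bs)
    per$twave_area_sim[i] <- window_area(ts, windows$twave, bs)
  }
  summ <- lapply(per[-1], function(v)
    if (any(is.finite(v))) summarize_stats(v) else NULL)
  structure(list(per_site = per, summary = summ, windows = windows),
            class = "morphology_report")
}

#' Timing-morphology correlations
#'
#' Pearson correlation between activation time and signed QRS area, and
#' between repolarization time and signed T-wave area, across valid sites.
#' The forward model predicts these to be strongly positive and strongly
#' negative respectively: sites that activate before the remote component
#' show QS complexes (negative area), late-activating sites prominent R
#' waves; early-repolarizing sites show positive T-waves, late ones
#' negative.
#'
#' @param markers a `marker_map` from [mark_all()].
#' @param qrs_area,twave_area per-site signed areas (mV*ms) aligned with
#'   `markers` rows.
#' @param min_sites minimum number of valid sites (default 10).
#' @return list with `cc_at_qrsa`, `cc_rt_twa`, `n`, `valid`.
#' @export
timing_area_maps <- function(markers, qrs_area, twave_area, min_sites = 10) {
  ok <- markers$valid & is.finite(qrs_area) & is.finite(twave_area)
  if (sum(ok) < min_sites)
    return(list(cc_at_qrsa = NA_real_, cc_rt_twa = NA_real_,
                n = sum(ok), valid = FALSE))
  a <- pearson_cc(markers$AT_ms[ok], qrs_area[ok])
  r <- pearson_cc(markers$RT_ms[ok], twave_area[ok])
  list(cc_at_qrsa = a$cc, cc_rt_twa = r$cc, n = sum(ok),
       valid = a$valid && r$valid)
}
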