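#' QRS and T-wave analysis windows
#'
#' @param qrs `[start, end]` in ms relative to the stimulus.
#' @param twave `[start, end]` in ms; must start at or after the QRS window
#'   ends.
#' @return An object of class `beat_windows`.
#' @export
beat_windows <- function(qrs, twave) {
  if (length(qrs) != 2L || length(twave) != 2L ||
      qrs[2] <= qrs[1] || twave[2] <= twave[1])
    stop("windows must be increasing [start, end] pairs in ms")
  if (qrs[2] > twave[1])
    stop("the QRS window must end before the T-wave window starts")
  structure(list(qrs = as.numeric(qrs), twave = as.numeric(twave)),
            class = "beat_windows")
}

#' Automatic QRS/T-wave window split
#'
#' For unattended runs no prior marker information is available, so the
#' windows are bootstrapped from the signals themselves.  The activation
#' upstroke is far steeper than any repolarization slope, so a first pass
#' locates every site's intrinsic deflection as the global minimum of
#' dV/dt over the whole (artifact-blanked) beat.  The QRS window then runs
#' from 10 ms before the earliest such deflection to `qrs_tail_ms` after
#' the latest one, and the T-wave window from there to `guard_ms` before
#' the end of the beat.
#'
#' @param signals a [signal_matrix()] of stimulus-aligned averaged beats.
#' @param artifact_ms initial blanking to skip the pacing artifact (ms).
#' @param guard_ms guard band dropped at the end of the beat (ms).
#' @param qrs_tail_ms span allowed for the terminal QRS rebound after the
#'   latest intrinsic deflection (ms).
#' @return A [beat_windows()] object.
#' @export
auto_windows <- function(signals, artifact_ms = 10, guard_ms = 20,
                         qrs_tail_ms = 30) {
  stopifnot(inherits(signals, "signal_matrix"))
  t <- time_axis(signals)
  t_end <- max(t) - guard_ms
  usable <- which(t >= artifact_ms & t <= t_end)
  if (length(usable) < 10L) stop("beat too short to window")
  at0 <- apply(signals$samples, 1, function(v) {
    d <- num_deriv(v, signals$fs)[usable]
    t[usable][which.min(d)]
  })
  t_split <- max(at0) + qrs_tail_ms
  if (t_split >= t_end - 3000 / signals$fs)
    stop("no room left for a T-wave window after the QRS")
  beat_windows(qrs = c(max(artifact_ms, min(at0) - 10), t_split),
               twave = c(t_split, t_end))
}

#' Activation time from a unipolar electrogram
#'
#' AT is the interval between the pacing stimulus and the time of the
#' minimum of the first derivative of the UEG within the QRS complex
#' (steepest negative deflection, the intrinsic deflection).  Ties are
#' broken by the earliest sample.
#'
#' @param trace a [signal_trace()].
#' @param qrs_window `[start, end]` ms.
#' @param flat_eps derivative range (mV/ms) below which the window is
#'   declared flat and the marker invalid.
#' @return list with `AT` (ms, NA if invalid), `valid`, `reason`.
#' @export
detect_at <- function(trace, qrs_window, flat_eps = 1e-9) {
  stopifnot(inherits(trace, "signal_trace"))
  idx <- window_idx(qrs_window, trace$fs, trace$t0, length(trace$samples))
  d <- num_deriv(trace$samples, trace$fs)[idx]
  if (diff(range(d)) < flat_eps)
    return(list(AT = NA_real_, valid = FALSE, reason = "flat"))
  t <- time_axis(trace)[idx]
  list(AT = t[which.min(d)], valid = TRUE, reason = "")
}

#' Repolarization time from a unipolar electrogram (Wyatt method)
#'
#' RT is the time of the maximum of the first derivative within the T-wave,
#' independently of T-wave polarity: the same rule localises the upslope of
#' positive, biphasic and negative T-waves.  Ties are broken by the earliest
#' sample.
#'
#' @inheritParams detect_at
#' @param twave_window `[start, end]` ms.
#' @return list with `RT` (ms, NA if invalid), `valid`, `reason`.
#' @export
detect_rt <- function(trace, twave_window, flat_eps = 1e-9) {
  stopifnot(inherits(trace, "signal_trace"))
  idx <- window_idx(twave_window, trace$fs, trace$t0, length(trace$samples))
  d <- num_deriv(trace$samples, trace$fs)[idx]
  if (diff(range(d)) < flat_eps)
    return(list(RT = NA_real_, valid = FALSE, reason = "flat"))
  t <- time_axis(trace)[idx]
  list(RT = t[which.max(d)], valid = TRUE, reason = "")
}

#' Activation-recovery interval
#'
#' ARI = RT - AT, the standard surrogate for local action-potential
#' duration.  Invalid (with reason `"negative_ari"`) when RT does not
#' exceed AT.
#'
#' @param at activation time (ms).
#' @param rt repolarization time (ms).
#' @return list with `ARI` (ms, NA if invalid), `valid`, `reason`.
#' @export
compute_ari <- function(at, rt) {
  if (is.na(at) || is.na(rt))
    return(list(ARI = NA_real_, valid = FALSE, reason = "missing_marker"))
  if (rt <= at)
    return(list(ARI = NA_real_, valid = FALSE, reason = "negative_ari"))
  list(ARI = rt - at, valid = TRUE, reason = "")
}

#' Measure AT, RT and ARI on every site
#'
#' Applies [detect_at()], [detect_rt()] and [compute_ari()] row-wise to a
#' matrix of signal-averaged beats.  Per-site failures are flagged, never
#' fatal.
#'
#' @param signals a [signal_matrix()] of QC-passed, signal-averaged beats.
#' @param windows a [beat_windows()] object (see [auto_windows()]).
#' @return A `marker_map`: data.frame with columns `site_id`, `AT_ms`,
#'   `RT_ms`, `ARI_ms`, `valid`, `reason`.
#' @export
mark_all <- function(signals, windows) {
  stopifnot(inherits(signals, "signal_matrix"),
            inherits(windows, "beat_windows"))
  m <- nrow(signals$samples)
  out <- data.frame(site_id = signals$site_id,
                    AT_ms = rep(NA_real_, m), RT_ms = rep(NA_real_, m),
                    ARI_ms = rep(NA_real_, m), valid = rep(FALSE, m),
                    reason = rep("", m), stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    tr <- get_trace(signals, i)
    a <- detect_at(tr, windows$qrs)
    r <- detect_rt(tr, windows$twave)
    out$AT_ms[i] <- a$AT
    out$RT_ms[i] <- r$RT
    if (!a$valid || !r$valid) {
      out$reason[i] <- paste(c(a$reason, r$reason)[c(!a$valid, !r$valid)],
                             collapse = ";")
      next
    }
    k <- compute_ari(a$AT, r$RT)
    out$ARI_ms[i] <- k$ARI
    out$valid[i] <- k$valid
    out$reason[i] <- k$reason
  }
  class(out) <- c("marker_map", "data.frame")
  out
}
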