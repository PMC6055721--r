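#' Quality-control configuration
#'
#' Thresholds and bands for beat-stability filtering and spectral SNR
#' filtering of unipolar electrograms.
#'
#' @param stability_cc_min minimum mean Pearson correlation between each
#'   beat and the per-sample median beat (default 0.98); sites below are
#'   rejected as beat-to-beat unstable.
#' @param snr_min_db minimum spectral signal-to-noise ratio in dB
#'   (default 10).
#' @param signal_band signal frequency band in Hz (default 1-40).
#' @param noise_band noise frequency band in Hz (default 40-100).
#' @param n_discard_initial_beats paced beats dropped at the start of each
#'   drive train to approximate steady state (default 5).
#' @param snr_on_average compute SNR on the signal-averaged beat (default
#'   TRUE) rather than on the median single beat.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(stability_cc_min = 0.98, snr_min_db = 10,
                      signal_band = c(1, 40), noise_band = c(40, 100),
                      n_discard_initial_beats = 5, snr_on_average = TRUE) {
  if (stability_cc_min <= 0 || stability_cc_min > 1)
    stop("stability_cc_min must be in (0, 1]")
  if (length(signal_band) != 2L || length(noise_band) != 2L ||
      diff(signal_band) <= 0 || diff(noise_band) <= 0)
    stop("bands must be increasing [lo, hi] pairs in Hz")
  if (signal_band[2] > noise_band[1])
    stop("signal and noise bands must not overlap")
  structure(list(stability_cc_min = stability_cc_min,
                 snr_min_db = snr_min_db,
                 signal_band = as.numeric(signal_band),
                 noise_band = as.numeric(noise_band),
                 n_discard_initial_beats = n_discard_initial_beats,
                 snr_on_average = snr_on_average),
            class = "qc_config")
}

#' Segment a continuous paced recording into stimulus-aligned beats
#'
#' Cuts one beat of `cycle_length` ms after each stimulus, dropping the
#' first `n_discard` beats of the drive train and any stimulus whose beat
#' would run past the end of the recording.
#'
#' @param raw a [signal_matrix()] of continuous recordings (sites x
#'   samples), `t0` = time of the first sample.
#' @param stim_times stimulus times in ms, sorted increasing.
#' @param cycle_length pacing cycle length in ms.
#' @param n_discard initial beats to drop (default 0; the pipeline passes
#'   the [qc_config()] value).
#' @return A `beat_stack`: list with `beats` (sites x beats x samples
#'   array), `fs`, `cycle_length`, `site_id`, `stim_times` (of the beats
#'   kept).
#' @export
segment_beats <- function(raw, stim_times, cycle_length, n_discard = 0) {
  stopifnot(inherits(raw, "signal_matrix"))
  if (length(stim_times) == 0L) stop("stimulus list is empty")
  if (is.unsorted(stim_times)) stop("stim_times must be sorted")
  spb <- round(cycle_length * raw$fs / 1000)      # samples per beat
  n <- ncol(raw$samples)
  start <- round((stim_times - raw$t0) * raw$fs / 1000) + 1L
  ok <- start >= 1L & (start + spb - 1L) <= n
  start <- start[ok]
  stim_times <- stim_times[ok]
  if (n_discard > 0 && length(start) > n_discard) {
    start <- start[-seq_len(n_discard)]
    stim_times <- stim_times[-seq_len(n_discard)]
  }
  if (length(start) < 2L)
    stop("fewer than 2 usable beats after segmentation")
  m <- nrow(raw$samples)
  beats <- array(NA_real_, dim = c(m, length(start), spb))
  for (b in seq_along(start))
    beats[, b, ] <- raw$samples[, start[b]:(start[b] + spb - 1L), drop = FALSE]
  structure(list(beats = beats, fs = raw$fs, cycle_length = cycle_length,
                 site_id = raw$site_id, stim_times = stim_times),
            class = "beat_stack")
}

# beats-by-samples matrix for one site of a beat_stack
site_beats <- function(stack, i) {
  matrix(stack$beats[i, , ], nrow = dim(stack$beats)[2])
}

#' Beat-to-beat stability filter for one site
#'
#' Computes the per-sample median beat, then the mean over beats of the
#' Pearson correlation between each beat and that median beat.  Sites whose
#' mean correlation falls below `stability_cc_min` show beat-to-beat
#' morphological variability and are rejected.  A zero-variance beat has an
#' undefined correlation; it is scored 0 and a warning is raised.
#'
#' @param beats beats x samples numeric matrix for one site.
#' @param cfg a [qc_config()].
#' @return list with `keep` (logical) and `mean_cc`.
#' @export
stability_filter <- function(beats, cfg = qc_config()) {
  beats <- as.matrix(beats)
  if (nrow(beats) < 2L) stop("stability filter needs at least 2 beats")
  med <- apply(beats, 2, stats::median)
  if (stats::sd(med) == 0) {
    warning("median beat has zero variance; site scored mean cc = 0")
    return(list(keep = FALSE, mean_cc = 0))
  }
  cc <- apply(beats, 1, function(b) {
    if (stats::sd(b) == 0) {
      warning("zero-variance beat scored cc = 0")
      return(0)
    }
    stats::cor(b, med)
  })
  mean_cc <- mean(cc)
  list(keep = mean_cc >= cfg$stability_cc_min, mean_cc = mean_cc)
}

#' Welch power spectral density estimate
#'
#' Mean of modified periodograms over Hann-windowed segments with 50%
#' overlap; one-sided density scaling.  Traces shorter than `nperseg`
#' are estimated from a single full-length segment.
#'
#' @param x numeric sample vector.
#' @param fs sampling frequency in Hz.
#' @param nperseg segment length in samples (default `min(fs, length(x))`,
#'   i.e. 1-second segments).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(round(fs), length(x)),
                      overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  if (nperseg < 8L) stop("trace too short for a PSD estimate")
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- signal::hanning(nperseg)
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 * scale
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when nperseg even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nperseg %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = acc / length(starts))
}

band_power <- function(freq, psd, band) {
  idx <- which(freq >= band[1] & freq <= band[2])
  if (length(idx) < 2L) stop("fewer than 2 PSD bins in band")
  pracma::trapz(freq[idx], psd[idx])
}

#' Spectral signal-to-noise ratio
#'
#' `SNR_dB = 10 log10(P_signal / P_noise)` where the band powers are the
#' Welch PSD integrated over the signal band (1-40 Hz by default, where the
#' QRS and T-wave live) and the noise band (40-100 Hz).  Zero noise-band
#' power yields +Inf (kept, with a warning).
#'
#' @param trace a [signal_trace()] (typically the signal-averaged beat).
#' @param cfg a [qc_config()].
#' @return list with `snr_db` and `keep`.
#' @export
spectral_snr <- function(trace, cfg = qc_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  p <- welch_psd(trace$samples, trace$fs)
  ps <- band_power(p$freq, p$psd, cfg$signal_band)
  pn <- band_power(p$freq, p$psd, cfg$noise_band)
  if (pn <= 0) {
    warning("zero power in the noise band; SNR = +Inf")
    return(list(snr_db = Inf, keep = TRUE))
  }
  snr <- 10 * log10(ps / pn)
  list(snr_db = snr, keep = snr >= cfg$snr_min_db)
}

#' Signal averaging of a beat stack
#'
#' Per-sample mean over beats; reduces uncorrelated background noise by
#' about `1/sqrt(n_beats)`.
#'
#' @param beats beats x samples matrix for one site.
#' @return numeric vector, the averaged beat.
#' @export
signal_average <- function(beats) {
  beats <- as.matrix(beats)
  colMeans(beats)
}

#' Run the full QC chain over a beat stack
#'
#' For every site: beat-stability filter, signal averaging, spectral SNR
#' filter.  QC decisions use only the site's own beats.
#'
#' @param stack a `beat_stack` from [segment_beats()].
#' @param cfg a [qc_config()].
#' @return list with `averaged` (a [signal_matrix()] of all sites'
#'   signal-averaged beats) and `report` (data.frame: `site_id`, `mean_cc`,
#'   `snr_db`, `kept`, `reason`).
#' @export
qc_filter <- function(stack, cfg = qc_config()) {
  stopifnot(inherits(stack, "beat_stack"))
  m <- dim(stack$beats)[1]
  spb <- dim(stack$beats)[3]
  avg <- matrix(NA_real_, m, spb)
  rep_df <- data.frame(site_id = stack$site_id, mean_cc = NA_real_,
                       snr_db = NA_real_, kept = FALSE, reason = "",
                       stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    b <- site_beats(stack, i)
    st <- suppressWarnings(stability_filter(b, cfg))
    rep_df$mean_cc[i] <- st$mean_cc
    avg[i, ] <- signal_average(b)
    src <- if (cfg$snr_on_average) avg[i, ] else apply(b, 2, stats::median)
    sn <- suppressWarnings(
      spectral_snr(signal_trace(src, fs = stack$fs), cfg))
    rep_df$snr_db[i] <- sn$snr_db
    rep_df$kept[i] <- st$keep && sn$keep
    rep_df$reason[i] <- paste(c(if (!st$keep) "unstable",
                                if (!sn$keep) "low_snr"), collapse = ";")
  }
  list(averaged = signal_matrix(avg, fs = stack$fs, t0 = 0,
                                site_id = stack$site_id),
       report = rep_df)
}
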