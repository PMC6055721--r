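#' Uniformly sampled voltage trace
#'
#' Lightweight container for a single electrogram or action-potential trace:
#' a numeric sample vector plus its sampling frequency and the time of the
#' first sample relative to the pacing stimulus.
#'
#' @param samples numeric vector of voltages (mV unless stated otherwise).
#' @param fs sampling frequency in Hz (default 1000, the acquisition rate of
#'   epicardial sock recordings).
#' @param t0 time of the first sample in ms relative to the stimulus.
#' @param units voltage units label, informational only.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, fs = 1000, t0 = 0, units = "mV") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a signal_trace needs at least 2 samples")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(samples = samples, fs = fs, t0 = t0, units = units),
            class = "signal_trace")
}

#' Multichannel signal matrix (sites x samples)
#'
#' One row per cardiac site, all rows sharing the sampling grid.
#'
#' @param samples numeric matrix, sites in rows, samples in columns.
#' @param fs sampling frequency in Hz.
#' @param t0 time of the first column in ms relative to the stimulus.
#' @param units voltage units label.
#' @param site_id optional site identifiers (default `1:nrow`).
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(samples, fs = 1000, t0 = 0, units = "mV",
                          site_id = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 2L) stop("a signal_matrix needs at least 2 samples")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(site_id)) site_id <- seq_len(nrow(samples))
  if (length(site_id) != nrow(samples))
    stop("site_id length must match the number of rows")
  structure(list(samples = samples, fs = fs, t0 = t0, units = units,
                 site_id = site_id),
            class = "signal_matrix")
}

#' Time axis of a trace or matrix
#'
#' @param x a `signal_trace` or `signal_matrix`.
#' @return numeric vector of sample times in ms relative to the stimulus.
#' @export
time_axis <- function(x) {
  n <- if (inherits(x, "signal_matrix")) ncol(x$samples) else length(x$samples)
  x$t0 + (seq_len(n) - 1) * 1000 / x$fs
}

#' Extract one site from a signal matrix as a trace
#'
#' @param x a `signal_matrix`.
#' @param i row index.
#' @return a `signal_trace`.
#' @export
get_trace <- function(x, i) {
  stopifnot(inherits(x, "signal_matrix"))
  signal_trace(x$samples[i, ], fs = x$fs, t0 = x$t0, units = x$units)
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("signal_trace: %d samples @ %g Hz, t0 = %g ms [%s]\n",
              length(x$samples), x$fs, x$t0, x$units))
  invisible(x)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d sites x %d samples @ %g Hz, t0 = %g ms [%s]\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$t0, x$units))
  invisible(x)
}

#' @export
plot.signal_trace <- function(x, ...) {
  graphics::plot(time_axis(x), x$samples, type = "l",
                 xlab = "time (ms)", ylab = paste0("V (", x$units, ")"), ...)
}

# first time derivative in units/ms: central differences inside, one-sided
# stencils at the boundaries (unbiased extremum localisation).
num_deriv <- function(v, fs) {
  n <- length(v)
  dt <- 1000 / fs
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

# convert a [start, end] ms window to column indices on a trace grid
window_idx <- function(window, fs, t0, n) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be an increasing [start, end] pair in ms")
  t <- t0 + (seq_len(n) - 1) * 1000 / fs
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) < 3L) stop("window covers fewer than 3 samples")
  idx
}
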