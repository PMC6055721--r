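#' Shared action-potential shape parameters
#'
#' The stylized action potential is the product of two logistic functions —
#' one for the depolarization upstroke, one for the repolarization
#' downslope — shifted by the resting potential.  Within a beat the shape
#' parameters are position-independent: every site shares `A`, `V_rest`,
#' `beta_AT` and `beta_RT`, and differs only in its local activation and
#' repolarization times.
#'
#' @param A action-potential amplitude in mV.  The default 100 mV together
#'   with `V_rest = 80` gives a plateau near +20 mV and rest near -80 mV;
#'   morphology correlations and polarity predictions are invariant to this
#'   choice.
#' @param V_rest resting potential magnitude in mV (subtracted from the
#'   product of logistics).
#' @param beta_AT upstroke steepness in 1/ms (default 0.4, the center of the
#'   search grid used by [beta_grid()]).
#' @param beta_RT downslope steepness in 1/ms (default 0.035).  Activation
#'   is much steeper than repolarization, so `beta_AT > beta_RT` is
#'   enforced.
#' @return An object of class `ap_params`.
#' @seealso [stylized_ap()], [beta_grid()]
#' @export
ap_params <- function(A = 100, V_rest = 80, beta_AT = 0.4, beta_RT = 0.035) {
  if (!is.finite(A) || A <= 0) stop("A must be positive")
  if (!is.finite(beta_AT) || beta_AT <= 0) stop("beta_AT must be positive")
  if (!is.finite(beta_RT) || beta_RT <= 0) stop("beta_RT must be positive")
  if (beta_AT <= beta_RT)
    stop("beta_AT must exceed beta_RT (activation is steeper than repolarization)")
  structure(list(A = A, V_rest = V_rest, beta_AT = beta_AT, beta_RT = beta_RT),
            class = "ap_params")
}

#' Conductivity balance and the UEG scaling factor
#'
#' The unipolar electrogram is a rescaled difference between the local
#' action potential and the remote component; the scale is
#' `alpha = g_i / (g_i + g_e)`, the balance between intracellular and
#' extracellular conductivities, assumed constant in space and time.  The
#' default `g_i = 1, g_e = 3` gives `alpha = 0.25`, the value used in all
#' configurations here.
#'
#' @param g_i intracellular conductivity (arbitrary units, > 0).
#' @param g_e extracellular conductivity (same units, > 0).
#' @return An object of class `conductivity_scaling` with fields `g_i`,
#'   `g_e` and the derived `alpha`.
#' @export
conductivity_scaling <- function(g_i = 1, g_e = 3) {
  if (!is.finite(g_i) || g_i <= 0) stop("g_i must be positive")
  if (!is.finite(g_e) || g_e <= 0) stop("g_e must be positive")
  structure(list(g_i = g_i, g_e = g_e, alpha = g_i / (g_i + g_e)),
            class = "conductivity_scaling")
}

as_alpha <- function(scaling) {
  if (inherits(scaling, "conductivity_scaling")) return(scaling$alpha)
  a <- as.numeric(scaling)
  if (length(a) != 1L || !is.finite(a) || a <= 0 || a >= 1)
    stop("alpha must be a single number in (0, 1)")
  a
}

check_grid <- function(time_grid) {
  if (length(time_grid) < 2L) stop("time grid needs at least 2 points")
  dt <- diff(time_grid)
  if (any(abs(dt - dt[1]) > 1e-9 * abs(dt[1])) || dt[1] <= 0)
    stop("time grid must be uniform and increasing")
  dt[1]
}

#' Stylized local action potential
#'
#' Evaluates
#' `AP(t) = A / (1 + exp(-beta_AT (t - tau_AT))) *
#'  (1 - 1 / (1 + exp(-beta_RT (t - tau_RT)))) - V_rest`
#' on a uniform time grid.  The first logistic is the depolarization
#' upstroke (steepest at `tau_AT`), the second the repolarization downslope
#' (steepest at `tau_RT`).
#'
#' @param time_grid uniform time grid in ms relative to the stimulus.
#' @param params an [ap_params()] object.
#' @param tau_AT local activation time (ms).
#' @param tau_RT local repolarization time (ms); must exceed `tau_AT`.
#' @return A [signal_trace()] on the same grid.
#' @export
stylized_ap <- function(time_grid, params, tau_AT, tau_RT) {
  stopifnot(inherits(params, "ap_params"))
  dt <- check_grid(time_grid)
  if (!is.finite(tau_AT) || !is.finite(tau_RT) || tau_RT <= tau_AT)
    stop("tau_RT must exceed tau_AT")
  up <- stats::plogis(params$beta_AT * (time_grid - tau_AT))
  down <- 1 - stats::plogis(params$beta_RT * (time_grid - tau_RT))
  signal_trace(params$A * up * down - params$V_rest,
               fs = 1000 / dt, t0 = time_grid[1])
}

#' Ensemble of stylized action potentials
#'
#' One action potential per cardiac site, all sharing the same shape
#' parameters (position-independent) and differing only in their local
#' activation/repolarization times.
#'
#' @param time_grid uniform time grid in ms.
#' @param params an [ap_params()] object shared by all sites.
#' @param timings data.frame with columns `tau_AT` and `tau_RT` (ms), one
#'   row per site.  An optional `site_id` column is carried through.
#' @return An object of class `ap_ensemble`: a [signal_matrix()]-like list
#'   with fields `samples` (M x T matrix), `fs`, `t0`, `timings`, `params`.
#' @export
ap_ensemble <- function(time_grid, params, timings) {
  stopifnot(inherits(params, "ap_params"))
  timings <- as.data.frame(timings)
  if (nrow(timings) < 1L) stop("need at least one site timing")
  if (!all(c("tau_AT", "tau_RT") %in% names(timings)))
    stop("timings must have columns tau_AT and tau_RT")
  dt <- check_grid(time_grid)
  bad <- which(timings$tau_RT <= timings$tau_AT)
  if (length(bad))
    stop("tau_RT must exceed tau_AT at every site (first offender: row ",
         bad[1], ")")
  # M x T via two outer products: logistic(beta * (t - tau)) row-wise
  up <- stats::plogis(params$beta_AT *
                        outer(-timings$tau_AT, time_grid, `+`))
  down <- 1 - stats::plogis(params$beta_RT *
                              outer(-timings$tau_RT, time_grid, `+`))
  m <- params$A * up * down - params$V_rest
  site_id <- if ("site_id" %in% names(timings)) timings$site_id
             else seq_len(nrow(timings))
  structure(list(samples = m, fs = 1000 / dt, t0 = time_grid[1],
                 units = "mV", site_id = site_id,
                 timings = timings, params = params),
            class = c("ap_ensemble", "signal_matrix"))
}

#' Remote component: the mean action potential
#'
#' The remote component representing distant electrical activity is
#' position-independent and equal to the pointwise arithmetic mean of the
#' local action potentials over all cardiac sites.
#'
#' @param ensemble an [ap_ensemble()] (or any `signal_matrix`).
#' @return A [signal_trace()] on the ensemble grid.
#' @export
remote_component <- function(ensemble) {
  stopifnot(inherits(ensemble, "signal_matrix"))
  signal_trace(colMeans(ensemble$samples), fs = ensemble$fs,
               t0 = ensemble$t0, units = ensemble$units)
}

#' Simulate unipolar electrograms from an action-potential ensemble
#'
#' The UEG at site i is the inverted, rescaled difference between the local
#' action potential and the remote component:
#' `UEG_i(t) = -alpha * (AP_i(t) - mean_AP(t))`.
#' Because the remote component is the ensemble mean, the UEGs sum to zero
#' across sites at every sample, and for two sites they are exact mirror
#' images.
#'
#' @param ensemble an [ap_ensemble()].
#' @param scaling a [conductivity_scaling()] object or a bare alpha in
#'   (0, 1).  Default alpha = 0.25.
#' @return A [signal_matrix()] of UEGs on the ensemble grid, carrying the
#'   ensemble `site_id`.
#' @export
simulate_ueg <- function(ensemble, scaling = conductivity_scaling()) {
  stopifnot(inherits(ensemble, "signal_matrix"))
  alpha <- as_alpha(scaling)
  remote <- colMeans(ensemble$samples)
  ueg <- -alpha * sweep(ensemble$samples, 2, remote, `-`)
  signal_matrix(ueg, fs = ensemble$fs, t0 = ensemble$t0,
                units = ensemble$units, site_id = ensemble$site_id)
}

#' Simulate UEGs directly from site timings
#'
#' Convenience wrapper: builds the stylized-AP ensemble on a 1 kHz beat
#' grid `[0, cycle_length)` and returns the simulated UEG matrix.  Sites
#' whose repolarization tail extends past the beat window are truncated
#' with a warning.
#'
#' @param timings data.frame with `tau_AT`, `tau_RT` (ms).
#' @param cycle_length beat window length in ms.
#' @param params an [ap_params()].
#' @param scaling a [conductivity_scaling()] or bare alpha.
#' @param fs sampling frequency in Hz.
#' @return A [signal_matrix()] of UEGs.
#' @export
ueg_from_timings <- function(timings, cycle_length,
                             params = ap_params(),
                             scaling = conductivity_scaling(),
                             fs = 1000) {
  t <- seq(0, cycle_length - 1000 / fs, by = 1000 / fs)
  # tail extent where the downslope logistic is still > 1% off its asymptote
  tail_ms <- 4.6 / params$beta_RT
  if (any(timings$tau_RT + tail_ms > cycle_length))
    warning("repolarization tail of ", sum(timings$tau_RT + tail_ms > cycle_length),
            " site(s) extends past the beat window and is truncated")
  simulate_ueg(ap_ensemble(t, params, timings), scaling)
}
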