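#' Steepness-parameter search grid
#'
#' The candidate upstroke/downslope steepness pairs.  Defaults are the
#' standard 3 x 4 grid: `beta_AT` in {0.2, 0.4, 0.6} and `beta_RT` in
#' {0.025, 0.035, 0.045, 0.055} ms^-1.
#'
#' @param beta_AT_values candidate upstroke steepness values (1/ms).
#' @param beta_RT_values candidate downslope steepness values (1/ms).
#' @return An object of class `beta_grid`.
#' @export
beta_grid <- function(beta_AT_values = c(0.2, 0.4, 0.6),
                      beta_RT_values = c(0.025, 0.035, 0.045, 0.055)) {
  if (any(beta_AT_values <= 0) || any(beta_RT_values <= 0))
    stop("all beta values must be positive")
  if (length(beta_AT_values) == 0L || length(beta_RT_values) == 0L)
    stop("grid must be nonempty")
  structure(list(beta_AT_values = sort(beta_AT_values),
                 beta_RT_values = sort(beta_RT_values)),
            class = "beta_grid")
}

#' Grid search for the position-independent steepness pair
#'
#' For every `(beta_AT, beta_RT)` pair the model simulates UEGs from the
#' measured per-site AT/RT markers and scores the pair by the median
#' whole-beat Pearson correlation against the recorded (signal-averaged)
#' UEGs; the pair with the highest median correlation — best morphological
#' matching — wins.  Ties go to the smaller `beta_AT`, then the smaller
#' `beta_RT`.  The scaling factor alpha stays fixed during the search.
#'
#' @param recorded a [signal_matrix()] of signal-averaged beats.
#' @param markers a `marker_map` from [mark_all()] on those beats; only
#'   valid sites are used.
#' @param grid a [beta_grid()].
#' @param scaling a [conductivity_scaling()] or bare alpha (default 0.25).
#' @param artifact_ms post-stimulus exclusion for the correlations.
#' @param ap shared amplitude/resting-potential parameters; only `A` and
#'   `V_rest` are taken from it (the betas come from the grid).
#' @return list with `beta_AT`, `beta_RT`, `median_cc`, and `scores`
#'   (data.frame: beta_AT, beta_RT, median_cc, n_sites).
#' @export
grid_search_beta <- function(recorded, markers, grid = beta_grid(),
                             scaling = conductivity_scaling(),
                             artifact_ms = 10, ap = ap_params()) {
  stopifnot(inherits(recorded, "signal_matrix"),
            inherits(grid, "beta_grid"))
  ok <- markers$valid
  if (sum(ok) < 10L) stop("grid search needs at least 10 valid sites")
  timings <- data.frame(tau_AT = markers$AT_ms[ok],
                        tau_RT = markers$RT_ms[ok])
  rec <- recorded$samples[ok, , drop = FALSE]
  t <- time_axis(recorded)
  use <- which(t >= artifact_ms)
  alpha <- as_alpha(scaling)
  combos <- expand.grid(beta_RT = grid$beta_RT_values,
                        beta_AT = grid$beta_AT_values)[, 2:1]
  combos <- combos[order(combos$beta_AT, combos$beta_RT), ]
  scores <- data.frame(beta_AT = combos$beta_AT, beta_RT = combos$beta_RT,
                       median_cc = NA_real_, n_sites = sum(ok))
  for (k in seq_len(nrow(combos))) {
    p <- ap_params(A = ap$A, V_rest = ap$V_rest,
                   beta_AT = combos$beta_AT[k], beta_RT = combos$beta_RT[k])
    sim <- simulate_ueg(ap_ensemble(t, p, timings), alpha)
    cc <- vapply(seq_len(nrow(rec)), function(i)
      pearson_cc(rec[i, use], sim$samples[i, use])$cc, numeric(1))
    scores$median_cc[k] <- stats::median(cc, na.rm = TRUE)
  }
  # rows are in (beta_AT, beta_RT) order, so the first strict maximum
  # realises the smaller-beta tie-break
  best <- which.max(scores$median_cc)
  list(beta_AT = scores$beta_AT[best], beta_RT = scores$beta_RT[best],
       median_cc = scores$median_cc[best], scores = scores)
}
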