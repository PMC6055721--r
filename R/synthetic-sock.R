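#' Synthetic sock-dataset generator configuration
#'
#' Parameters of the synthetic epicardial-sock acquisition: geometry,
#' activation spread, repolarization field, and the nuisance processes
#' (noise, wander, jitter, corrupted channels) that exercise the QC chain.
#'
#' @param n_sites number of electrodes over the two ventricles (default
#'   240).
#' @param cycle_length pacing cycle length in ms, 350-600.
#' @param n_beats beats per S1 drive train (default 30; trains of 30-50 are
#'   typical).
#' @param pacing_site index of the paced electrode; `NULL` picks the
#'   apex-most site.
#' @param conduction_velocity apparent epicardial conduction velocity in
#'   mm/ms (default 1.0, which over an apex-to-base path of ~95 mm spreads
#'   activation across roughly 60-120 ms).
#' @param apd_base baseline action-potential duration in ms; `NULL` uses a
#'   restitution-like default `120 + 0.25 * cycle_length`.
#' @param apd_gradient apex-to-base APD increase in ms (default 20).
#' @param apd_at_coupling slope of APD against local activation time
#'   (default -0.35): later-activated sites have shorter APD, so
#'   repolarization dispersion stays below activation dispersion.
#' @param spatial_noise_sd sd of the spatially correlated timing noise (ms).
#' @param beat_jitter_sd sd of the per-beat timing jitter (ms).
#' @param additive_noise_sd sd of the additive measurement noise (mV),
#'   low-pass filtered at 100 Hz.
#' @param baseline_wander_amp,baseline_wander_freq respiratory-like
#'   baseline wander amplitude (mV) and frequency (Hz).
#' @param n_corrupt_channels channels deliberately corrupted (alternating
#'   morphology or in-band interference) to exercise the QC filters.
#' @param ap_shape_jitter fractional per-site perturbation of the logistic
#'   steepness parameters, so the pseudo-recorded signals are not the
#'   simple model itself.
#' @param stim_artifact_mv amplitude of the 2 ms biphasic pacing artifact.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_sites = 240, cycle_length = 600,
                             n_beats = 30, pacing_site = NULL,
                             conduction_velocity = 1.0,
                             apd_base = NULL, apd_gradient = 20,
                             apd_at_coupling = -0.45,
                             spatial_noise_sd = 4, beat_jitter_sd = 1,
                             additive_noise_sd = 0.05,
                             baseline_wander_amp = 0.3,
                             baseline_wander_freq = 0.3,
                             n_corrupt_channels = 4,
                             ap_shape_jitter = 0.15,
                             stim_artifact_mv = 2) {
  if (n_sites < 2) stop("need at least 2 sites")
  if (is.null(apd_base)) apd_base <- 120 + 0.25 * cycle_length
  sds <- c(spatial_noise_sd, beat_jitter_sd, additive_noise_sd,
           baseline_wander_amp)
  if (any(sds < 0)) stop("noise amplitudes must be nonnegative")
  cfg <- list(n_sites = n_sites, cycle_length = cycle_length,
              n_beats = n_beats, pacing_site = pacing_site,
              conduction_velocity = conduction_velocity,
              apd_base = apd_base, apd_gradient = apd_gradient,
              apd_at_coupling = apd_at_coupling,
              spatial_noise_sd = spatial_noise_sd,
              beat_jitter_sd = beat_jitter_sd,
              additive_noise_sd = additive_noise_sd,
              baseline_wander_amp = baseline_wander_amp,
              baseline_wander_freq = baseline_wander_freq,
              n_corrupt_channels = n_corrupt_channels,
              ap_shape_jitter = ap_shape_jitter,
              stim_artifact_mv = stim_artifact_mv)
  class(cfg) <- "generator_config"
  cfg
}

#' Electrode positions on a two-ventricle surrogate surface
#'
#' Quasi-uniform points on a base-truncated ellipsoid (semi-axes
#' 35 x 35 x 55 mm, apex at negative z) laid out along a golden-angle
#' spiral, with a small seeded positional jitter so the lattice is not
#' artificially regular.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return data.frame with `site_id`, `x`, `y`, `z` (mm).
#' @export
gen_geometry <- function(cfg = generator_config(), seed = 1) {
  n <- cfg$n_sites
  a <- 35; b <- 35; cax <- 55
  z_hi <- 0.6                       # truncate above this fraction (base)
  set.seed(seed)
  i <- seq_len(n)
  u <- -1 + (i - 0.5) * (1 + z_hi) / n      # cos(polar) in [-1, z_hi]
  phi <- i * pi * (3 - sqrt(5))             # golden angle
  s <- sqrt(pmax(0, 1 - u^2))
  pts <- cbind(x = a * s * cos(phi), y = b * s * sin(phi), z = cax * u)
  pts <- pts + matrix(stats::rnorm(3 * n, sd = 0.5), n, 3)
  data.frame(site_id = i, x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

# spatially correlated zero-mean field with unit sd via Gaussian-kernel
# smoothing of iid normals over the electrode cloud
smooth_field <- function(geometry, length_scale = 15) {
  d <- as.matrix(stats::dist(geometry[, c("x", "y", "z")]))
  w <- exp(-d^2 / (2 * length_scale^2))
  z <- stats::rnorm(nrow(geometry))
  f <- as.numeric(w %*% z) / rowSums(w)
  f <- f - mean(f)
  if (stats::sd(f) > 0) f / stats::sd(f) else f
}

#' Ground-truth activation and repolarization fields
#'
#' Activation spreads from the pacing site at the configured conduction
#' velocity (straight-line distances over the electrode cloud), plus a
#' smooth correlated perturbation.  Repolarization is activation plus an
#' APD field with an apex-to-base gradient, a restitution-like negative
#' coupling to local activation time, and its own smooth perturbation.
#' Repolarization must fit inside the beat window.
#'
#' @param geometry from [gen_geometry()].
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @param rt_dispersion_max optional cap (ms) on the repolarization
#'   dispersion `max(tau_RT) - min(tau_RT)`: when the realized field
#'   exceeds it, repolarization times are shrunk linearly around their
#'   mean.  Used to hold an experiment inside a stated dispersion regime.
#' @return data.frame (`truth` marker map) with `site_id`, `tau_AT`,
#'   `tau_RT` in ms.
#' @export
gen_timing_fields <- function(geometry, cfg = generator_config(), seed = 1,
                              rt_dispersion_max = NULL) {
  set.seed(seed + 1L)
  pace <- cfg$pacing_site
  if (is.null(pace)) pace <- which.min(geometry$z)
  dx <- geometry$x - geometry$x[pace]
  dy <- geometry$y - geometry$y[pace]
  dz <- geometry$z - geometry$z[pace]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  tau_AT <- 5 + dist / cfg$conduction_velocity +
    cfg$spatial_noise_sd * smooth_field(geometry)
  tau_AT <- pmax(tau_AT, 1)
  zn <- (geometry$z - min(geometry$z)) / diff(range(geometry$z)) - 0.5
  apd <- cfg$apd_base + cfg$apd_gradient * zn +
    cfg$apd_at_coupling * (tau_AT - mean(tau_AT)) +
    5 * smooth_field(geometry)
  tau_RT <- tau_AT + apd
  if (!is.null(rt_dispersion_max)) {
    disp <- diff(range(tau_RT))
    if (disp > rt_dispersion_max)
      tau_RT <- mean(tau_RT) +
        (tau_RT - mean(tau_RT)) * rt_dispersion_max / disp
    if (any(tau_RT <= tau_AT))
      stop("rt_dispersion_max too tight: repolarization before activation")
  }
  if (any(tau_RT >= cfg$cycle_length))
    stop("configuration puts repolarization beyond the cycle length")
  data.frame(site_id = geometry$site_id, tau_AT = tau_AT, tau_RT = tau_RT)
}

#' Pseudo-recorded multi-beat electrograms
#'
#' Builds a paced recording deliberately richer than the forward model it
#' will be validated against: per-site perturbed logistic steepness
#' (`ap_shape_jitter`), per-beat timing jitter, additive low-passed
#' measurement noise, sinusoidal baseline wander with per-site phase, a
#' 2 ms biphasic pacing artifact, and `n_corrupt_channels` corrupted
#' channels — alternating-morphology channels that trip the beat-stability
#' filter and in-band (70 Hz) interference channels that trip the SNR
#' filter.
#'
#' @param truth from [gen_timing_fields()].
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @param params shared [ap_params()]; the betas are the per-site
#'   perturbation centers.
#' @return list with `raw` (continuous [signal_matrix()]), `stim_times`
#'   (ms), `stack` (`beat_stack` of all beats), and `corrupt` (data.frame:
#'   `site_id`, `type`).
#' @export
gen_pseudo_recorded <- function(truth, cfg = generator_config(), seed = 1,
                                params = ap_params()) {
  set.seed(seed + 2L)
  m <- nrow(truth)
  fs <- 1000
  spb <- round(cfg$cycle_length * fs / 1000)
  nb <- cfg$n_beats
  total <- nb * spb
  tbeat <- (seq_len(spb) - 1) * 1000 / fs

  jit <- cfg$ap_shape_jitter
  bAT <- params$beta_AT * (1 + stats::runif(m, -jit, jit))
  bRT <- params$beta_RT * (1 + stats::runif(m, -jit, jit))

  corrupt <- data.frame(site_id = integer(0), type = character(0))
  if (cfg$n_corrupt_channels > 0) {
    idx <- sample(m, min(cfg$n_corrupt_channels, m))
    type <- rep(c("alternans", "noise"), length.out = length(idx))
    corrupt <- data.frame(site_id = truth$site_id[idx], type = type,
                          stringsAsFactors = FALSE)
  }

  raw <- matrix(0, m, total)
  for (b in seq_len(nb)) {
    tau_AT <- truth$tau_AT + stats::rnorm(m, sd = cfg$beat_jitter_sd)
    tau_RT <- truth$tau_RT + stats::rnorm(m, sd = cfg$beat_jitter_sd)
    tau_RT <- pmax(tau_RT, tau_AT + 20)
    up <- stats::plogis(sweep(outer(bAT, tbeat), 1, bAT * tau_AT, `-`))
    down <- 1 - stats::plogis(sweep(outer(bRT, tbeat), 1, bRT * tau_RT, `-`))
    apm <- params$A * up * down - params$V_rest
    ueg <- -0.25 * sweep(apm, 2, colMeans(apm), `-`)
    alt <- corrupt$site_id[corrupt$type == "alternans"]
    if (length(alt) && b %% 2L == 0L)
      ueg[match(alt, truth$site_id), ] <- -ueg[match(alt, truth$site_id), ]
    # biphasic pacing artifact in the first 2 ms
    ueg[, 1] <- ueg[, 1] + cfg$stim_artifact_mv
    ueg[, 2] <- ueg[, 2] - cfg$stim_artifact_mv
    raw[, ((b - 1) * spb + 1):(b * spb)] <- ueg
  }

  if (cfg$additive_noise_sd > 0) {
    bf <- signal::butter(4, 2 * 100 / fs, type = "low")
    noise <- matrix(stats::rnorm(m * total, sd = cfg$additive_noise_sd),
                    m, total)
    for (i in seq_len(m))
      noise[i, ] <- signal::filtfilt(bf, noise[i, ])
    raw <- raw + noise
  }
  if (cfg$baseline_wander_amp > 0) {
    tt <- (seq_len(total) - 1) / fs
    phase <- stats::runif(m, 0, 2 * pi)
    raw <- raw + cfg$baseline_wander_amp *
      sin(outer(phase, 2 * pi * cfg$baseline_wander_freq * tt, `+`))
  }
  nz <- corrupt$site_id[corrupt$type == "noise"]
  if (length(nz)) {
    tt <- (seq_len(total) - 1) / fs
    raw[match(nz, truth$site_id), ] <-
      raw[match(nz, truth$site_id), , drop = FALSE] +
      matrix(rep(5 * sin(2 * pi * 70 * tt), length(nz)),
             nrow = length(nz), byrow = TRUE)
  }

  stim_times <- (seq_len(nb) - 1) * cfg$cycle_length
  raw_sm <- signal_matrix(raw, fs = fs, t0 = 0, site_id = truth$site_id)
  stack <- segment_beats(raw_sm, stim_times, cfg$cycle_length)
  list(raw = raw_sm, stim_times = stim_times, stack = stack,
       corrupt = corrupt)
}

#' Generate a complete synthetic sock dataset
#'
#' Geometry, ground-truth timing fields and a multi-beat pseudo-recorded
#' signal matrix, fully reproducible from `(seed, cfg)`.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return An object of class `sock_dataset`: list with `geometry`,
#'   `truth`, `raw`, `stim_times`, `stack`, `corrupt`, `config`, `seed`.
#' @export
synthetic_sock <- function(cfg = generator_config(), seed = 1) {
  geometry <- gen_geometry(cfg, seed)
  truth <- gen_timing_fields(geometry, cfg, seed)
  rec <- gen_pseudo_recorded(truth, cfg, seed)
  structure(list(geometry = geometry, truth = truth, raw = rec$raw,
                 stim_times = rec$stim_times, stack = rec$stack,
                 corrupt = rec$corrupt, config = cfg, seed = seed),
            class = "sock_dataset")
}

#' @export
print.sock_dataset <- function(x, ...) {
  cat(sprintf(paste0("sock_dataset: %d sites, CL %g ms, %d beats, ",
                     "%d corrupt channel(s), seed %d\n"),
              x$config$n_sites, x$config$cycle_length, x$config$n_beats,
              nrow(x$corrupt), x$seed))
  invisible(x)
}
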