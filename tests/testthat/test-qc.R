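test_that("segmentation slices one aligned beat per stimulus", {
  fs <- 1000; cl <- 600; nb <- 30
  m <- matrix(rnorm(2 * nb * cl / 1), nrow = 2)
  raw <- signal_matrix(m, fs = fs, t0 = 0)
  stim <- (0:(nb - 1)) * cl
  st <- segment_beats(raw, stim, cl)
  expect_equal(dim(st$beats), c(2, 30, 600))
  # content round-trip: beat b is exactly the matching raw slice
  expect_equal(st$beats[1, 7, ], m[1, (6 * 600 + 1):(7 * 600)])
  expect_error(segment_beats(raw, numeric(0), cl), "empty")
  # initial-beat discard
  st5 <- segment_beats(raw, stim, cl, n_discard = 5)
  expect_equal(dim(st5$beats)[2], 25)
  expect_equal(st5$beats[1, 1, ], st$beats[1, 6, ])
})

test_that("stability filter keeps identical beats and rejects variability", {
  beat <- sin(2 * pi * (0:499) / 500)
  same <- matrix(rep(beat, 10), 10, byrow = TRUE)
  st <- stability_filter(same)
  expect_true(st$keep)
  expect_equal(st$mean_cc, 1)
  # alternating morphology: the median beat degenerates and the site fails
  alt <- same
  alt[seq(2, 10, 2), ] <- -same[seq(2, 10, 2), ]
  expect_warning(ra <- stability_filter(alt), "zero variance")
  expect_false(ra$keep)
  # ectopic transient scaled up until the 0.98 criterion trips
  ect <- same
  bump <- exp(-((0:499) - 250)^2 / 200)
  scale <- 0.1
  while (stability_filter(`[<-`(ect, 3, , bump * scale))$mean_cc >= 0.98 &&
         scale < 1e4)
    scale <- scale * 2
  ect[3, ] <- bump * scale
  res <- stability_filter(ect)
  expect_lt(res$mean_cc, 0.98)
  expect_false(res$keep)
  # zero-variance beat is scored 0 with a warning
  zv <- same
  zv[2, ] <- 5
  expect_warning(rz <- stability_filter(zv), "zero-variance")
  expect_lt(rz$mean_cc, 1)
})

test_that("spectral SNR separates in-band signal from out-of-band noise", {
  t <- (0:999) / 1000
  s10 <- spectral_snr(signal_trace(sin(2 * pi * 10 * t), fs = 1000))
  expect_gt(s10$snr_db, 10)
  expect_true(s10$keep)
  s60 <- spectral_snr(signal_trace(sin(2 * pi * 60 * t), fs = 1000))
  expect_lt(s60$snr_db, 0)
  expect_false(s60$keep)
  # white noise: flat PSD, so SNR ~ bandwidth ratio 10*log10(39/60)
  set.seed(11)
  wn <- spectral_snr(signal_trace(rnorm(60000), fs = 1000))
  expect_equal(wn$snr_db, 10 * log10(39 / 60), tolerance = 0.5)
  expect_false(wn$keep)
  # zero power everywhere: +Inf, kept, warned
  expect_warning(zz <- spectral_snr(signal_trace(rep(2, 1000), fs = 1000)),
                 "noise band")
  expect_true(is.infinite(zz$snr_db) && zz$keep)
})

test_that("signal averaging reduces iid noise by about 1/sqrt(n)", {
  set.seed(21)
  truth <- snap_ms(make_field(seed = 2, n_sites = 40))
  clean <- suppressWarnings(ueg_from_timings(truth, 600))$samples[1, ]
  n <- 25; sigma <- 0.5
  stack <- matrix(rep(clean, n), n, byrow = TRUE) +
    matrix(rnorm(n * length(clean), sd = sigma), n)
  resid <- signal_average(stack) - clean
  expect_equal(sd(resid) / (sigma / sqrt(n)), 1, tolerance = 0.2)
  # single beat: identity; identical beats: idempotent
  expect_equal(signal_average(matrix(clean, 1)), clean)
  expect_equal(signal_average(matrix(rep(clean, 4), 4, byrow = TRUE)), clean)
})

test_that("QC rejects corrupt channels, keeps clean ones, and is monotone", {
  ds <- synthetic_sock(generator_config(n_sites = 60, n_beats = 15), seed = 5)
  st <- segment_beats(ds$raw, ds$stim_times, ds$config$cycle_length,
                      n_discard = 5)
  q <- qc_filter(st)
  bad <- match(ds$corrupt$site_id, q$report$site_id)
  expect_true(all(!q$report$kept[bad]))
  clean <- setdiff(seq_len(60), bad)
  expect_gte(mean(q$report$kept[clean]), 0.95)
  # relaxing either threshold never decreases the retained count
  q_relax <- qc_filter(st, qc_config(stability_cc_min = 0.5, snr_min_db = -20))
  expect_gte(sum(q_relax$report$kept), sum(q$report$kept))
  # the two filter families each catch their constructed violator
  alt_site <- ds$corrupt$site_id[ds$corrupt$type == "alternans"][1]
  nz_site <- ds$corrupt$site_id[ds$corrupt$type == "noise"][1]
  expect_lt(q$report$mean_cc[match(alt_site, q$report$site_id)], 0.98)
  expect_lt(q$report$snr_db[match(nz_site, q$report$site_id)], 10)
})
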