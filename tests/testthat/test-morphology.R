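test_that("pearson_cc matches closed-form values and flags degeneracy", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cc(x, 2 * x + 3)$cc, 1)
  expect_equal(pearson_cc(x, -x)$cc, -1)
  expect_equal(pearson_cc(x, c(1, 3, 2))$cc, 0.5)  # hand computation
  flat <- pearson_cc(x, c(4, 4, 4))
  expect_false(flat$valid)
  expect_true(is.na(flat$cc))
  expect_error(pearson_cc(x, 1:4), "equal length")
})

test_that("window areas integrate signed voltage-time products", {
  v <- rep(1, 100)
  tr <- signal_trace(v, fs = 1000)
  expect_equal(window_area(tr, c(20, 30), baseline = 1), 0)
  # unit rectangle 10 ms wide above baseline 0
  expect_equal(window_area(tr, c(20, 30), baseline = 0), 10)
  # polarity reversal negates the area
  rect <- signal_trace(c(rep(0, 40), rep(2, 21), rep(0, 39)), fs = 1000)
  a <- window_area(rect, c(30, 70), 0)
  neg <- signal_trace(-rect$samples, fs = 1000)
  expect_equal(window_area(neg, c(30, 70), 0), -a)
})

test_that("distribution summaries follow the median/MAD/fence conventions", {
  s <- summarize_stats(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$mad, 1)          # median(|x - 3|) without scaling constant
  expect_equal(s$q1, 2)           # type-7 quartiles
  expect_equal(s$q3, 4)
  expect_equal(s$fence_lo, 2 - 3)
  expect_equal(s$fence_hi, 4 + 3)
  expect_equal(s$n_outliers, 0)
  const <- summarize_stats(rep(7, 10))
  expect_equal(const$mad, 0)
  expect_equal(const$n_outliers, 0)
  # one value beyond the upper fence flags exactly one outlier
  s2 <- summarize_stats(c(1, 2, 3, 4, 5, 100))
  expect_equal(s2$n_outliers, 1)
  expect_error(summarize_stats(numeric(0)), "no finite")
})

test_that("self-comparison is perfect and sign flip is anti-perfect", {
  truth <- snap_ms(make_field(seed = 3, n_sites = 50))
  ueg <- suppressWarnings(ueg_from_timings(truth, 600))
  w <- suppressWarnings(auto_windows(ueg, artifact_ms = 0))
  self <- morphology_compare(ueg, ueg, w, artifact_ms = 0)
  expect_true(all(abs(self$per_site$cc_whole - 1) < 1e-12))
  expect_true(all(abs(self$per_site$cc_qrs - 1) < 1e-12))
  expect_equal(self$per_site$qrs_area_rec, self$per_site$qrs_area_sim)
  flip <- signal_matrix(-ueg$samples, fs = ueg$fs, t0 = ueg$t0,
                        site_id = ueg$site_id)
  anti <- morphology_compare(ueg, flip, w, artifact_ms = 0)
  expect_true(all(abs(anti$per_site$cc_whole + 1) < 1e-12))
  expect_error(morphology_compare(ueg, signal_matrix(ueg$samples[1:10, ],
                                                     fs = ueg$fs), w),
               "site sets")
})

test_that("correlations are invariant to per-site affine rescaling", {
  truth <- snap_ms(make_field(seed = 4, n_sites = 30))
  ueg <- suppressWarnings(ueg_from_timings(truth, 600))
  w <- suppressWarnings(auto_windows(ueg, artifact_ms = 0))
  set.seed(8)
  other <- signal_matrix(ueg$samples +
                           matrix(rnorm(length(ueg$samples), sd = 0.1),
                                  nrow(ueg$samples)),
                         fs = ueg$fs, t0 = ueg$t0, site_id = ueg$site_id)
  base <- morphology_compare(ueg, other, w)
  gains <- runif(30, 0.5, 3)
  scaled <- signal_matrix(ueg$samples * gains + 7, fs = ueg$fs, t0 = ueg$t0,
                          site_id = ueg$site_id)
  resc <- morphology_compare(scaled, other, w)
  expect_equal(resc$per_site$cc_whole, base$per_site$cc_whole,
               tolerance = 1e-12)
  expect_equal(resc$per_site$cc_twave, base$per_site$cc_twave,
               tolerance = 1e-12)
})

test_that("increasing noise never improves the median whole-beat cc", {
  truth <- snap_ms(make_field(seed = 5, n_sites = 60))
  ueg <- suppressWarnings(ueg_from_timings(truth, 600))
  w <- suppressWarnings(auto_windows(ueg, artifact_ms = 0))
  amp <- max(abs(ueg$samples))
  set.seed(31)
  meds <- sapply(c(0.01, 0.05, 0.2) * amp, function(sd) {
    noisy <- signal_matrix(ueg$samples +
                             matrix(rnorm(length(ueg$samples), sd = sd),
                                    nrow(ueg$samples)),
                           fs = ueg$fs, t0 = ueg$t0, site_id = ueg$site_id)
    median(morphology_compare(noisy, ueg, w)$per_site$cc_whole)
  })
  expect_true(all(diff(meds) <= 0.005))
})

test_that("timing-area maps recover the polarity laws and flag degeneracy", {
  truth <- snap_ms(make_field(seed = 1, cl = 350))
  r <- suppressWarnings(marker_round_trip(truth, 350))
  mo <- morphology_compare(r$ueg, r$ueg, r$windows, artifact_ms = 0)
  tam <- timing_area_maps(r$markers, mo$per_site$qrs_area_sim,
                          mo$per_site$twave_area_sim)
  expect_gt(tam$cc_at_qrsa, 0.95)
  expect_lt(tam$cc_rt_twa, -0.9)
  # uniform timing: UEGs vanish, correlation undefined, flagged
  p <- ap_params()
  tg <- seq(0, 500, by = 1)
  same <- simulate_ueg(ap_ensemble(tg, p, data.frame(tau_AT = rep(100, 12),
                                                     tau_RT = rep(300, 12))))
  w <- beat_windows(c(0, 200), c(210, 480))
  mk <- mark_all(same, w)
  expect_true(all(!mk$valid))
  areas <- rep(0, 12)
  tam0 <- timing_area_maps(mk, areas, areas)
  expect_false(tam0$valid)
})
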