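test_that("stylized AP hits its logistic limit values", {
  p <- ap_params(A = 100, V_rest = 80, beta_AT = 0.4, beta_RT = 0.035)
  tg <- seq(0, 600, by = 1)
  ap <- stylized_ap(tg, p, tau_AT = 250, tau_RT = 470)
  v <- function(t) ap$samples[match(t, tg)]
  # far before activation: both logistics at their resting limits
  expect_lt(abs(v(50) - (-p$V_rest)), 1e-6 * p$A)
  # plateau between activation and repolarization (downslope logistic is
  # still ~0.997 at 170 ms before tau_RT)
  expect_lt(abs(v(300) - (p$A - p$V_rest)), 1e-2 * p$A)
  # half-amplitude at the upstroke center (downslope logistic ~ 1 there)
  expect_lt(abs(v(250) - (p$A / 2 - p$V_rest)), 1e-3 * p$A)
})

test_that("stylized AP rejects invalid inputs", {
  p <- ap_params()
  expect_error(stylized_ap(c(0, 1, 3), p, 10, 200), "uniform")
  expect_error(stylized_ap(0:500, p, 300, 200), "tau_RT")
  expect_error(ap_params(beta_AT = 0.02, beta_RT = 0.035), "beta_AT")
  expect_error(ap_params(A = -1), "A must")
})

test_that("steepest AP upslope sits at tau_AT (dense-grid oracle)", {
  p <- ap_params()
  tg <- seq(0, 500, by = 0.1)
  for (tau in c(120.0, 203.7, 310.2)) {
    ap <- stylized_ap(tg, p, tau_AT = tau, tau_RT = tau + 180)
    d <- diff(ap$samples) / 0.1
    t_peak <- tg[which.max(d)] + 0.05
    expect_lt(abs(t_peak - tau), 0.1 + 1e-9)
  }
})

test_that("ensemble APs are time-shifted copies when both taus shift", {
  p <- ap_params()
  tg <- seq(0, 600, by = 1)
  delta <- 40
  ens <- ap_ensemble(tg, p, data.frame(tau_AT = c(100, 100 + delta),
                                       tau_RT = c(320, 320 + delta)))
  n <- length(tg)
  a <- ens$samples[1, 1:(n - delta)]
  b <- ens$samples[2, (delta + 1):n]
  expect_lt(max(abs(a - b)), 1e-9 * p$A)
})

test_that("single-site ensemble reproduces stylized_ap and rows stay in range", {
  p <- ap_params()
  tg <- seq(0, 600, by = 1)
  one <- ap_ensemble(tg, p, data.frame(tau_AT = 90, tau_RT = 310))
  expect_equal(as.numeric(one$samples[1, ]),
               stylized_ap(tg, p, 90, 310)$samples)
  truth <- make_field(seed = 4)
  ens <- ap_ensemble(tg, p, truth)
  expect_equal(nrow(ens$samples), 240)
  expect_true(all(ens$samples >= -p$V_rest - 1e-9))
  expect_true(all(ens$samples <= p$A - p$V_rest + 1e-9))
  expect_error(ap_ensemble(tg, p, data.frame(tau_AT = numeric(0),
                                             tau_RT = numeric(0))),
               "at least one")
})

test_that("remote component is the pointwise site mean", {
  p <- ap_params()
  tg <- seq(0, 500, by = 1)
  same <- ap_ensemble(tg, p, data.frame(tau_AT = rep(100, 5),
                                        tau_RT = rep(300, 5)))
  expect_equal(remote_component(same)$samples,
               as.numeric(same$samples[1, ]))
  two <- ap_ensemble(tg, p, data.frame(tau_AT = c(80, 140),
                                       tau_RT = c(280, 340)))
  expect_equal(remote_component(two)$samples,
               as.numeric((two$samples[1, ] + two$samples[2, ]) / 2))
  # centering identity: mean over sites of (AP_i - remote) = 0 everywhere
  ens <- ap_ensemble(tg, p, data.frame(tau_AT = c(60, 100, 150),
                                       tau_RT = c(260, 300, 350)))
  centered <- sweep(ens$samples, 2, remote_component(ens)$samples, `-`)
  expect_lt(max(abs(colMeans(centered))), 1e-12 * p$A)
})

test_that("UEG matrix obeys the mean-subtraction identities", {
  p <- ap_params()
  tg <- seq(0, 500, by = 1)
  # identical timing at every site: zero UEGs
  same <- ap_ensemble(tg, p, data.frame(tau_AT = rep(110, 6),
                                        tau_RT = rep(320, 6)))
  expect_lt(max(abs(simulate_ueg(same)$samples)), 1e-12)
  ens <- ap_ensemble(tg, p, data.frame(tau_AT = c(60, 100, 150),
                                       tau_RT = c(260, 300, 350)))
  u1 <- simulate_ueg(ens, 0.25)
  u2 <- simulate_ueg(ens, 0.5)
  # alpha linearity
  expect_equal(u2$samples, 2 * u1$samples)
  # zero sum across sites at every sample
  expect_lt(max(abs(colSums(u1$samples))), 1e-9 * 0.25 * p$A)
  # two sites: exact antisymmetry
  two <- ap_ensemble(tg, p, data.frame(tau_AT = c(80, 140),
                                       tau_RT = c(280, 340)))
  ut <- simulate_ueg(two)
  expect_equal(ut$samples[1, ], -ut$samples[2, ])
})

test_that("QRS and T-wave polarity follow timing relative to the remote", {
  # three sites: early / middle / late activation and repolarization
  tg <- seq(0, 600, by = 1)
  ens <- ap_ensemble(tg, ap_params(),
                     data.frame(tau_AT = c(60, 110, 160),
                                tau_RT = c(280, 330, 380)))
  ueg <- simulate_ueg(ens)
  w <- beat_windows(qrs = c(0, 200), twave = c(210, 460))
  qrs_area <- sapply(1:3, function(i)
    window_area(get_trace(ueg, i), w$qrs, 0))
  tw_area <- sapply(1:3, function(i)
    window_area(get_trace(ueg, i), w$twave, 0))
  # earliest activation precedes the remote: QS (net-negative QRS);
  # latest follows it: prominent R (net-positive)
  expect_lt(qrs_area[1], 0)
  expect_gt(qrs_area[3], 0)
  expect_true(qrs_area[1] < qrs_area[2] && qrs_area[2] < qrs_area[3])
  # earliest repolarization: positive T-wave; latest: negative
  expect_gt(tw_area[1], 0)
  expect_lt(tw_area[3], 0)
})

test_that("conductivity scaling derives alpha and validates", {
  cs <- conductivity_scaling(1, 3)
  expect_equal(cs$alpha, 0.25)
  expect_error(conductivity_scaling(-1, 3), "g_i")
  expect_error(simulate_ueg(
    ap_ensemble(0:100, ap_params(),
                data.frame(tau_AT = 20, tau_RT = 60)), 1.5), "alpha")
})
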