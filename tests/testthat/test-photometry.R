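# dF/F, motion control, event detection.

test_that("spectral channel extraction integrates the right bands", {
  wl <- seq(480, 650, by = 1)
  # single spike at 520 nm lands entirely in the GCaMP band
  sp <- matrix(0, 2, length(wl))
  sp[, wl == 520] <- 7
  ch <- extract_channels(sp, wl)
  expect_equal(ch$F_gcamp, rep(7, 2))
  expect_equal(ch$F_mcherry, rep(0, 2))

  # flat spectrum: channel ratio equals band-width ratio (both 40 nm here)
  flat <- matrix(1, 1, length(wl))
  ch <- extract_channels(flat, wl)
  expect_equal(ch$F_gcamp / ch$F_mcherry, 1, tolerance = 1e-12)

  expect_error(extract_channels(flat, wl, gcamp_band = c(400, 540)),
               "outside")
})

test_that("two-Gaussian spectra are unmixed within 2% (quadrature oracle)", {
  wl <- seq(480, 650, by = 0.5)
  a_g <- 120; a_m <- 55
  g <- a_g * dnorm(wl, 515, 8) / dnorm(515, 515, 8)
  m <- a_m * dnorm(wl, 610, 9) / dnorm(610, 610, 9)
  sp <- matrix(g + m, 1, byrow = TRUE)
  ch <- extract_channels(sp, wl)
  # oracle: same quadrature applied to each pure component
  oracle_g <- extract_channels(matrix(g, 1), wl)$F_gcamp
  oracle_m <- extract_channels(matrix(m, 1), wl)$F_mcherry
  expect_lt(abs(ch$F_gcamp - oracle_g) / oracle_g, 0.02)
  expect_lt(abs(ch$F_mcherry - oracle_m) / oracle_m, 0.02)
})

test_that("compute_dff matches hand arithmetic and is scale-invariant", {
  d <- compute_dff(c(1, 2, 3))
  expect_equal(d$F0, 2)
  expect_equal(d$dff, c(-0.5, 0, 0.5))
  expect_equal(d$threshold, 3 * sd(d$dff))

  dc <- compute_dff(rep(4, 10))
  expect_equal(dc$dff, rep(0, 10))
  expect_equal(dc$threshold, 0)

  set.seed(5)
  for (i in 1:5) {
    F <- rlnorm(200, 3, 0.3)
    c_ <- runif(1, 0.1, 50)
    expect_equal(compute_dff(F)$dff, compute_dff(c_ * F)$dff,
                 tolerance = 1e-12)
  }
  expect_error(compute_dff(c(1)), "2 samples")
  expect_error(compute_dff(c(0, 0, 0)), "median")
  expect_error(compute_dff(c(-1, 2, 3)), "non-negative")
})

test_that("motion correction removes the mCherry-predicted component", {
  t <- seq(0, 99.9, by = 0.1)
  set.seed(2)
  mch <- 100 + 5 * sin(t / 3) + rnorm(length(t), 0, 1)
  dm <- compute_dff(mch)
  # gcamp exactly 2x mcherry: corrected trace is constant
  dg <- compute_dff(2 * mch)
  cr <- motion_correct(dg, dm)
  expect_lt(sd(cr$dff), 1e-12)

  # independent channels: slope ~ 0, trace ~ unchanged, and the OLS
  # residual is numerically orthogonal to the regressor
  g2 <- 100 + rnorm(length(t), 0, 2)
  dg2 <- compute_dff(g2)
  cr2 <- motion_correct(dg2, dm)
  expect_lt(abs(cr2$a), 0.05)
  expect_gt(cor(cr2$dff, dg2$dff), 0.99)
  expect_lt(abs(cor(cr2$dff, dm$dff)), 1e-10)

  dflat <- compute_dff(rep(10, length(t)) + 1e-15)
  expect_warning(motion_correct(dg2, dflat), "zero-variance")
  expect_false(suppressWarnings(motion_correct(dg2, dflat))$corrected)
})

test_that("motion correction improves event detection under shared artifact", {
  f1c <- f1u <- numeric(20)
  for (s in 1:20) {
    cfg <- quick_cfg(seed = s, photometry = list(
      duration_s = 300, motion_amp = 2, noise_sd = 0.02),
      genotype_params = list(WT = list(event_rate = 6, amplitude = 0.2,
                                       coupling = 0)))
    sim <- simulate_photometry_session(cfg, "WT", "DG")
    cor_ <- analyze_photometry_session(sim$session, motion_correct = TRUE)
    unc <- analyze_photometry_session(sim$session, motion_correct = FALSE)
    f1c[s] <- event_f1(cor_$events$onsets, sim$truth$event_times)
    f1u[s] <- event_f1(unc$events$onsets, sim$truth$event_times)
  }
  expect_gte(mean(f1c), mean(f1u))
})

test_that("event detection handles rectangles, empties, and monotonicity", {
  t <- seq(0, 9.9, by = 0.1)
  x <- rep(0, length(t))
  d <- structure(list(time = t, dff = x, F0 = 1, sd = 0.1,
                      threshold = 0.3, k_sd = 3), class = "septodg_dff")
  ev <- detect_events(d)
  expect_equal(ev$count, 0)
  expect_equal(ev$auc, 0)

  # one rectangular excursion: 10 samples, height threshold + 0.5
  x2 <- x; x2[31:40] <- 0.8
  d2 <- d; d2$dff <- x2
  ev2 <- detect_events(d2)
  expect_equal(ev2$count, 1)
  expect_equal(ev2$auc, 0.5 * 1.0, tolerance = 1e-9)
  expect_equal(ev2$peaks, 0.8)

  # count is non-increasing as the threshold multiplier k sweeps 1 -> 5
  set.seed(9)
  dffv <- as.numeric(arima.sim(list(ar = 0.8), 2000, sd = 0.05))
  dn <- structure(list(time = seq_along(dffv) / 10, dff = dffv, F0 = 1,
                       sd = sd(dffv), threshold = NA, k_sd = 3),
                  class = "septodg_dff")
  counts <- vapply(seq(1, 5, by = 0.5), function(k)
    detect_events(dn, threshold = k * sd(dffv))$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(detect_events(structure(list(dff = numeric(0)),
                                       class = "septodg_dff")), "empty")
})

test_that("AUC equals a sample-by-sample Riemann oracle", {
  set.seed(4)
  t <- seq(0, 19.9, by = 0.1)
  x <- pmax(rnorm(length(t), 0, 0.2), 0) + 0.1 * sin(t)
  thr <- 0.25
  d <- structure(list(time = t, dff = x, F0 = 1, sd = sd(x),
                      threshold = thr, k_sd = 3), class = "septodg_dff")
  ev <- detect_events(d)
  oracle <- sum(ifelse(x > thr, x - thr, 0)) * 0.1
  expect_equal(ev$auc, oracle, tolerance = 1e-12)
})

test_that("suprathreshold fraction on pure noise matches the normal tail", {
  # dff of Gaussian noise: P(dff > 3 sd) ~ pnorm(-3); Monte-Carlo over seeds
  fr <- vapply(1:40, function(s) {
    set.seed(s)
    d <- compute_dff(1000 + rnorm(5000))
    detect_events(d, min_dur_s = 0)$suprathreshold_frac
  }, numeric(1))
  p_tail <- pnorm(-3)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - p_tail), 3 * se + 1e-5)
})

test_that("well-separated transients are recovered and summarised", {
  cfg <- quick_cfg(seed = 21, photometry = list(
    duration_s = 600, noise_sd = 0.02, drift_amp = 0, motion_amp = 0),
    genotype_params = list(WT = list(event_rate = 0, amplitude = 0.1,
                                     coupling = 0)))
  onsets <- seq(10, 590, length.out = 30)
  sim <- simulate_photometry_session(cfg, "WT", "DG",
                                     events = data.frame(time = onsets,
                                                         amp = 0.15))
  res <- analyze_photometry_session(sim$session, motion_correct = FALSE)
  expect_lte(abs(res$events$count - 30), 1)
  act <- session_activity(res$events, 600)
  expect_equal(act$rate_per_min, res$events$count / 10)
  # trivial summaries
  ev0 <- detect_events(structure(list(time = 1:10 / 10, dff = rep(0, 10),
                                      threshold = 1, k_sd = 3),
                                 class = "septodg_dff"))
  a0 <- session_activity(ev0, 600)
  expect_equal(a0$rate_per_min, 0)
  expect_equal(a0$auc, 0)
})

test_that("two activity groups separate in a power simulation", {
  hits <- 0
  for (s in 1:25) {
    rates <- c(vapply(1:7, function(a) {
      cfg <- quick_cfg(seed = s * 100 + a, photometry = list(duration_s = 600),
                       genotype_params = list(WT = list(event_rate = 4,
                                                        amplitude = 0.5,
                                                        coupling = 0)))
      sim <- simulate_photometry_session(cfg, "WT", "DG")
      analyze_photometry_session(sim$session)$activity$rate_per_min
    }, numeric(1)),
    vapply(1:5, function(a) {
      cfg <- quick_cfg(seed = s * 100 + 50 + a,
                       photometry = list(duration_s = 600),
                       genotype_params = list(AD = list(event_rate = 8,
                                                        amplitude = 0.5,
                                                        coupling = 0)))
      sim <- simulate_photometry_session(cfg, "AD", "DG")
      analyze_photometry_session(sim$session)$activity$rate_per_min
    }, numeric(1)))
    cmp <- run_comparison(data.frame(value = rates,
                                     group = rep(c("WT", "AD"), c(7, 5))),
                          comparison_spec("unpaired_t", unit = "animal"))
    hits <- hits + (cmp$p < 0.05)
  }
  expect_gte(hits / 25, 0.8)
})
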