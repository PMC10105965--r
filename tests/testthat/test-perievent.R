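# Time-base alignment, trial matrices, bout responses, coupling.

make_dff <- function(dff, fs = 10) {
  structure(list(time = seq_along(dff) / fs - 1 / fs, dff = dff, F0 = 1,
                 sd = sd(dff), threshold = 3 * sd(dff), k_sd = 3),
            class = "septodg_dff")
}

test_that("bout boundaries snap to the photometry grid within 50 ms", {
  d <- make_dff(rep(0, 600))
  cfg <- quick_cfg(seed = 8)
  track <- simulate_behavior_track(cfg, n_bouts = 10)
  # onset 5.025 s snaps to the 5.0 s sample
  b <- data.frame(onset = 5.025, offset = 8.0, object = "A", duration = 2.975)
  al <- align_timebases(d, track, bouts = b)
  expect_equal(al$bouts$onset, 5.0)
  # random bout times: snapping error always <= half a photometry sample
  set.seed(1)
  b2 <- data.frame(onset = runif(50, 1, 50), offset = runif(50, 51, 55),
                   object = "A", duration = 1)
  al2 <- align_timebases(d, track, bouts = b2)
  expect_true(all(abs(al2$bouts$onset - b2$onset) <= 0.05 + 1e-12))
  expect_error(align_timebases(make_dff(rep(0, 10)), track,
                               bouts = b),  NA)  # overlapping ranges fine
  d_late <- make_dff(rep(0, 100)); d_late$time <- d_late$time + 1000
  expect_error(align_timebases(d_late, track), "overlap")
})

test_that("peri-event matrices have the documented geometry", {
  d <- make_dff(rep(0.7, 400))
  b <- data.frame(onset = c(10, 20), offset = c(13, 23),
                  object = c("A", "B"), duration = 3)
  pem <- build_perievent(d, b, window = c(-2, 2), scale = "none")
  expect_equal(ncol(pem$mat), 41)  # inclusive grid at 10 Hz
  pem2 <- build_perievent(d, b, window = c(-2, 4))
  expect_equal(ncol(pem2$mat), 61)
  expect_true(all(pem$mat == 0.7))          # constant trace -> constant rows
  expect_equal(as.numeric(colMeans(pem$mat)), rep(0.7, 41))

  # bouts near the trace edge are dropped and counted
  b3 <- rbind(b, data.frame(onset = 0.5, offset = 3.5, object = "A",
                            duration = 3))
  pem3 <- build_perievent(d, b3, window = c(-2, 4))
  expect_equal(nrow(pem3$mat), 2)
  expect_equal(pem3$dropped, 1)
  expect_error(build_perievent(d, b3[3, , drop = FALSE], window = c(-2, 4)),
               "retained")
})

test_that("bout-locked averages peak near the kernel peak", {
  cfg <- quick_cfg(seed = 31, photometry = list(noise_sd = 0.01,
                                                drift_amp = 0,
                                                motion_amp = 0),
                   genotype_params = list(WT = list(event_rate = 0,
                                                    amplitude = 0.5,
                                                    coupling = 0)))
  track <- simulate_behavior_track(cfg, n_bouts = 20)
  # transients locked to bout onsets only
  sim <- simulate_photometry_session(
    cfg, "WT", "DG", track = track,
    events = data.frame(time = track$bouts$onset, amp = 0.5))
  d <- compute_dff(sim$session$F_gcamp, sim$session$time)
  al <- align_timebases(d, track)
  pem <- build_perievent(d, al$bouts)
  avg <- colMeans(pem$mat)
  t_peak_kernel <- with(cfg$photometry,
                        rise_s * decay_s / (decay_s - rise_s) *
                          log(decay_s / rise_s))
  expect_lt(abs(pem$t[which.max(avg)] - t_peak_kernel), 0.3)
})

test_that("bout responses are baseline-subtracted in-bout means", {
  # zero trace -> zero response; 0 pre / 0.4 during -> 0.4
  d <- make_dff(rep(0, 300))
  b <- data.frame(onset = 10, offset = 13, object = "A", duration = 3)
  pem <- build_perievent(d, b)
  expect_equal(bout_response(pem), 0)
  x <- rep(0, 300); x[101:131] <- 0.4     # t in [10, 13]
  pem2 <- build_perievent(make_dff(x), b)
  expect_equal(bout_response(pem2), 0.4, tolerance = 1e-9)
  expect_equal(bout_response(pem2, baseline = FALSE), 0.4, tolerance = 1e-9)
})

test_that("fitted responses track true amplitudes at low noise", {
  cfg <- quick_cfg(seed = 17, photometry = list(noise_sd = 0.02,
                                                motion_amp = 0.5))
  track <- simulate_behavior_track(cfg, n_bouts = 20)
  pair <- simulate_paired_sessions(cfg, track, rho = 0.8)
  d <- analyze_photometry_session(pair$dg$session)$dff
  al <- align_timebases(d, track)
  pem <- build_perievent(d, al$bouts)
  resp <- bout_response(pem)
  expect_gte(cor(resp, pair$bout_amps$dg_amp), 0.9)
})

test_that("coupling handles exact, orthogonal, and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(coupling(x, x)$r, 1)
  # constructed orthogonality
  a <- c(-1, 1, -1, 1); b <- c(1, 1, -1, -1)
  expect_equal(coupling(a, b)$r, 0)
  z <- coupling(rep(1, 5), x)
  expect_true(z$undefined)
  expect_error(coupling(c(1, 2), c(1, 2)), "at least 3")
  expect_error(coupling(1:4, 1:5), "paired")
  # r invariant under affine rescaling of either input
  set.seed(3)
  u <- rnorm(30); v <- 0.6 * u + rnorm(30, 0, 0.5)
  expect_equal(coupling(u, v)$r, coupling(2 * u - 5, v)$r, tolerance = 1e-12)
  expect_equal(coupling(u, v)$r, coupling(u, -0.3 * v + 2)$r * -1,
               tolerance = 1e-12)
})

test_that("heat-map scaling never alters coupling statistics", {
  cfg <- quick_cfg(seed = 23)
  track <- simulate_behavior_track(cfg, n_bouts = 15)
  pair <- simulate_paired_sessions(cfg, track, rho = 0.8)
  d <- compute_dff(pair$dg$session$F_gcamp, pair$dg$session$time)
  m <- compute_dff(pair$ms$session$F_gcamp, pair$ms$session$time)
  al <- align_timebases(d, track)
  rs <- lapply(c("none", "minmax", "z"), function(sc) {
    pd <- build_perievent(d, al$bouts, scale = sc)
    pm <- build_perievent(m, al$bouts, scale = sc)
    coupling(bout_response(pd), bout_response(pm))$r
  })
  expect_equal(rs[[1]], rs[[2]])
  expect_equal(rs[[1]], rs[[3]])
})

test_that("encoding/retrieval dissociation is recovered across seeds", {
  hits_enc <- hits_ret <- 0
  n_rep <- 15
  for (s in 1:n_rep) {
    cfg <- quick_cfg(seed = 1000 + s)
    track <- simulate_behavior_track(cfg, n_bouts = 20,
                                     seed = child_seed(1000 + s, "tr"))
    for (rho in c(0.8, 0)) {
      pair <- simulate_paired_sessions(cfg, track, rho = rho,
                                       seed = child_seed(1000 + s,
                                                         paste0("p", rho)))
      d <- analyze_photometry_session(pair$dg$session)$dff
      m <- analyze_photometry_session(pair$ms$session)$dff
      al <- align_timebases(d, track)
      cp <- coupling(bout_response(build_perievent(d, al$bouts)),
                     bout_response(build_perievent(m, al$bouts)))
      if (rho == 0.8 && isTRUE(cp$sig)) hits_enc <- hits_enc + 1
      if (rho == 0 && !isTRUE(cp$sig)) hits_ret <- hits_ret + 1
    }
  }
  expect_gte(hits_enc / n_rep, 0.8)
  expect_gte(hits_ret / n_rep, 0.8)
})
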