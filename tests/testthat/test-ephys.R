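# sIPSC detection, opto contrasts, intrinsic properties, F-I comparison.

test_that("access-resistance QC applies the 20% rule strictly", {
  expect_true(qc_access_resistance(c(10, 11))$pass)
  expect_false(qc_access_resistance(c(10, 13))$pass)
  expect_true(qc_access_resistance(c(10, 12))$pass)   # exactly 20% passes
  expect_true(is.na(qc_access_resistance(10)$pass))
})

test_that("sIPSC detector: empty, injected, and false-positive regimes", {
  # all-zero trace
  tb0 <- detect_sipscs(rep(0, 20000))
  expect_equal(nrow(tb0), 0)

  # 10 injected 50 pA events on quiet baseline: full recall, tight amps
  cfg <- quick_cfg(seed = 3, ephys = list(amp_meanlog = log(50),
                                          amp_sdlog = 0, noise_sd_pA = 2))
  sim <- simulate_sipsc_trace(cfg, 12, event_times = seq(1, 10, by = 1))
  tb <- detect_sipscs(sim$sweeps$traces[[1]])
  expect_equal(nrow(tb), 10)
  expect_lt(abs(mean(tb$amplitude) - 50), 2)
  expect_true(all(abs(sort(tb$time) - seq(1, 10, by = 1)) < 0.01))

  # frequency x duration equals count exactly
  expect_equal(attr(tb, "frequency_hz") * attr(tb, "duration"), 10)

  # event-free noise: < 0.2 false positives per second
  fp <- vapply(1:5, function(s) {
    cfgn <- quick_cfg(seed = s, ephys = list(sipsc_rate = 0,
                                             noise_sd_pA = 2))
    sn <- simulate_sipsc_trace(cfgn, 30)
    nrow(detect_sipscs(sn$sweeps$traces[[1]])) / 30
  }, numeric(1))
  expect_lt(mean(fp), 0.2)
})

test_that("detected count is non-increasing in the threshold k", {
  cfg <- quick_cfg(seed = 5)
  sim <- simulate_sipsc_trace(cfg, 30)
  counts <- vapply(c(2.5, 3.5, 5, 7, 10), function(k)
    nrow(detect_sipscs(sim$sweeps$traces[[1]], k = k)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("group stats: KS self-distance and discrimination power", {
  mk_tb <- function(amps, dur = 60) {
    tb <- data.frame(time = seq_along(amps), amplitude = amps,
                     iei = c(NA, diff(seq_along(amps))))
    class(tb) <- c("septodg_event_table", "data.frame")
    attr(tb, "duration") <- dur
    attr(tb, "frequency_hz") <- nrow(tb) / dur
    tb
  }
  set.seed(2)
  amps <- rlnorm(100, log(40), 0.3)
  tabs <- list(mk_tb(amps), mk_tb(amps), mk_tb(amps), mk_tb(amps))
  gs <- sipsc_group_stats(tabs, c("WT", "WT", "AD", "AD"))
  ks_rows <- gs$comparisons[gs$comparisons$test == "ks_two_sample", ]
  expect_equal(ks_rows$statistic, c(0, 0))     # identical pooled samples

  # N(0,1) vs N(1,1) with n = 500: KS rejects essentially always
  rej <- vapply(1:20, function(s) {
    set.seed(s)
    d <- data.frame(value = c(rnorm(500), rnorm(500, 1)),
                    group = rep(c("a", "b"), each = 500))
    run_comparison(d, comparison_spec("ks_two_sample"))$p < 0.05
  }, logical(1))
  expect_true(all(rej))
  expect_error(sipsc_group_stats(tabs[1:2], c("WT", "AD")), "2 cells")
})

test_that("opto epoch contrast finds modulation and respects boundaries", {
  lp <- light_protocol(60)
  tabs <- lapply(1:8, function(ci) {
    cfg <- quick_cfg(seed = 400 + ci, ephys = list(opto_mod = 0.5))
    sim <- simulate_sipsc_trace(cfg, 60, light = lp)
    detect_sipscs(sim$sweeps$traces[[1]])
  })
  res <- opto_epoch_compare(tabs, lp)
  frow <- res$comparisons[res$comparisons$measure == "frequency_pre_vs_light", ]
  expect_lt(frow$p, 0.05)
  expect_true(all(res$per_cell$light_freq < res$per_cell$pre_freq))

  # an event exactly at epoch onset is counted in the light window
  tb <- data.frame(time = 20, amplitude = 50, iei = NA_real_)
  class(tb) <- c("septodg_event_table", "data.frame")
  attr(tb, "duration") <- 60
  er <- septodg:::epoch_rates(tb, lp)
  expect_equal(er$light_freq, 1 / 20)
  expect_equal(er$pre_freq, 0)
})

test_that("intrinsic properties recover the generator's cell", {
  cfg <- quick_cfg(ephys = list(R_Mohm = 150, tau_ms = 20,
                                rheobase_pA = 110, noise_sd_mV = 0))
  sim <- simulate_current_steps(cfg)
  ip <- intrinsic_properties(sim$sweeps)
  expect_lt(abs(ip$rin_Mohm - 150) / 150, 0.01)
  expect_lt(abs(ip$tau_ms - 20) / 20, 0.05)
  expect_equal(ip$capacitance_pF, ip$tau_ms / ip$rin_Mohm * 1000)
  expect_lt(abs(ip$capacitance_pF - sim$truth$C_pF) / sim$truth$C_pF, 0.06)
  expect_equal(ip$rmp_mV, cfg$ephys$rmp_mV, tolerance = 0.01)
  expect_equal(ip$rheobase_pA, sim$truth$rheobase_step_pA)
  expect_equal(ip$ap_threshold_mV, sim$truth$v_th, tolerance = 0.1)
  # F-I: zero below rheobase, positive and non-decreasing above
  expect_true(all(ip$fi$spikes[ip$fi$current_pA <= 100] == 0))
  expect_true(all(ip$fi$spikes[ip$fi$current_pA >= 120] > 0))
  expect_true(all(diff(ip$fi$spikes) >= 0))
  expect_equal(nrow(ip$fi), 16)
})

test_that("R = 100 MOhm is forced by a -2 mV deflection at -20 pA", {
  cfg <- quick_cfg(ephys = list(R_Mohm = 100, tau_ms = 20))
  ip <- intrinsic_properties(simulate_current_steps(cfg)$sweeps)
  expect_equal(ip$rin_Mohm, 100, tolerance = 0.5)
})

test_that("recovery error shrinks as generator noise goes to zero", {
  err <- function(ns) {
    e <- vapply(1:5, function(s) {
      cfg <- quick_cfg(seed = 40 + s,
                       ephys = list(R_Mohm = 150, tau_ms = 20,
                                    noise_sd_mV = ns))
      ip <- intrinsic_properties(simulate_current_steps(cfg)$sweeps)
      abs(ip$rin_Mohm - 150) / 150 + abs(ip$tau_ms - 20) / 20
    }, numeric(1))
    mean(e)
  }
  errs <- vapply(c(0.5, 0.05, 0), err, numeric(1))
  expect_true(all(diff(errs) < 0))       # mean error decreases with noise
  expect_lt(errs[3], 0.005)              # and vanishes on noiseless traces
})

test_that("F-I two-way ANOVA behaves at the design edges", {
  fi <- function(base) data.frame(current_pA = seq(-20, 280, 20),
                                  spikes = pmax(0, seq(-20, 280, 20) / 20 -
                                                  5 + base))
  tabs <- c(lapply(c(0, 1, 0, 1), fi), lapply(c(0, 1, 0, 1), fi))
  res <- fi_group_compare(tabs, rep(c("WT", "AD"), each = 4))
  grow <- res[res$effect == "genotype", ]
  expect_lt(grow$F, 1e-9)                  # identical groups

  res2 <- fi_group_compare(c(lapply(c(0, 1, 0, 1), fi),
                             lapply(c(6, 7, 6, 7), fi)),
                           rep(c("WT", "AD"), each = 4))
  expect_lt(res2[res2$effect == "genotype", "p"], 0.05)

  one_level <- lapply(1:4, function(i)
    data.frame(current_pA = 100, spikes = i))
  expect_error(fi_group_compare(one_level, c("WT", "WT", "AD", "AD")),
               "degenerate")
})

test_that("reduced-gain cells separate in the F-I comparison", {
  tabs <- list(); groups <- character(0)
  for (g in c("WT", "AD")) {
    for (ci in 1:9) {
      cfg <- quick_cfg(seed = 700 + ci + (g == "AD") * 50,
                       ephys = list(rheobase_pA = if (g == "WT") 110 else 150,
                                    tau_ms = 20 * exp(rnorm(1, 0, 0.05))))
      ip <- intrinsic_properties(simulate_current_steps(cfg)$sweeps)
      tabs[[paste0(g, ci)]] <- ip$fi
      groups <- c(groups, g)
    }
  }
  res <- fi_group_compare(tabs, groups)
  expect_lt(res[res$effect == "genotype", "p"], 0.05)
})
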