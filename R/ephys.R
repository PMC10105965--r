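# Voltage-clamp sIPSC analysis and current-clamp intrinsic properties.

#' Access-resistance quality control
#'
#' Cells are failed when access resistance changes by more than 20% between
#' the first and last checkpoint (strict inequality: exactly 20% passes).
#'
#' @param ra numeric vector of access-resistance checkpoints, MOhm (>= 2
#'   values required; fewer flags the cell unverifiable).
#' @param max_change fractional change tolerated (default 0.20).
#' @return list `pass` (logical, NA when unverifiable), `change`
#'   (fractional), `reason`.
#' @export
qc_access_resistance <- function(ra, max_change = 0.20) {
  ra <- ra[is.finite(ra)]
  if (length(ra) < 2)
    return(list(pass = NA, change = NA_real_,
                reason = "unverifiable: fewer than 2 checkpoints"))
  change <- abs(ra[length(ra)] - ra[1]) / ra[1]
  list(pass = change <= max_change + .Machine$double.eps^0.5,
       change = change,
       reason = if (change > max_change) "access resistance changed > 20%"
                else "ok")
}

# windowed-sinc FIR low-pass (Hamming), symmetric, unit DC gain
fir_lowpass <- function(x, fs, cutoff_hz = 1000, taps = 51) {
  m <- taps - 1
  k <- seq(0, m) - m / 2
  fc <- cutoff_hz / fs
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  h <- h * (0.54 - 0.46 * cos(2 * pi * seq(0, m) / m))
  h <- h / sum(h)
  pad <- m / 2
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[length(x) - seq_len(pad) + 1]))
  y <- stats::filter(xp, h, sides = 2)
  as.numeric(y[(pad + 1):(pad + length(x))])
}

#' Detect spontaneous IPSCs on a voltage-clamp trace
#'
#' The trace is low-pass filtered at 1 kHz; the baseline is a running
#' median; the noise SD is a robust (MAD-based) estimate of the raw
#' high-frequency residual.  Candidate events are maximal runs where the
#' *inward* deviation (baseline minus filtered signal) exceeds
#' `k * noise SD`; one event is taken per run at the deviation peak, and
#' peaks closer than `min_iei_ms` are merged into the larger one.
#' Amplitude is the positive magnitude `|peak - local baseline|` in pA.
#' Samples at the clip rails (if `clip_pA` is given) are excluded.
#'
#' @param trace data.frame (time, signal) or numeric vector, pA.
#' @param fs sampling rate, Hz (default 10000).
#' @param k detection threshold in noise SDs (default 3.5).
#' @param min_iei_ms minimum inter-event interval, ms (default 5).
#' @param baseline_s running-median window, s (default 0.2).
#' @param clip_pA optional c(lo, hi) saturation rails.
#' @return a `septodg_event_table` data.frame (time, amplitude, iei) with
#'   attributes `duration`, `noise_sd`, `threshold_pA`, `frequency_hz`.
#' @export
detect_sipscs <- function(trace, fs = 10000, k = 3.5, min_iei_ms = 5,
                          baseline_s = 0.2, clip_pA = NULL) {
  if (is.data.frame(trace)) { time <- trace$time; x <- trace$signal }
  else { x <- as.numeric(trace); time <- seq_along(x) / fs }
  n <- length(x)
  duration <- n / fs
  valid <- rep(TRUE, n)
  if (!is.null(clip_pA)) valid <- x > clip_pA[1] & x < clip_pA[2]

  filt <- fir_lowpass(x, fs, 1000)
  bw <- round(baseline_s * fs); if (bw %% 2 == 0) bw <- bw + 1
  base <- stats::runmed(filt, bw, endrule = "median")
  noise_sd <- mad_sd(x - base)
  thr <- k * noise_sd

  dev <- base - filt                       # positive for inward deflections
  above <- dev > thr & valid
  rr <- runs_true(above)
  pk_i <- integer(0); pk_a <- numeric(0)
  if (nrow(rr)) {
    pk_i <- vapply(seq_len(nrow(rr)), function(i) {
      w <- rr$start[i]:rr$end[i]; w[which.max(dev[w])]
    }, integer(1))
    pk_a <- dev[pk_i]
    # merge peaks within the minimum inter-event interval, and peaks on the
    # same excursion: a new event requires the deviation to have re-armed
    # (fallen below rearm * threshold) since the previous peak, so threshold
    # re-crossings on a decay tail do not double-count
    min_gap <- min_iei_ms / 1000 * fs
    rearm <- 0.5 * thr
    o <- order(pk_i)
    pk_i <- pk_i[o]; pk_a <- pk_a[o]
    keep <- rep(TRUE, length(pk_i))
    last <- 1L
    for (i in seq_along(pk_i)[-1]) {
      gap_ok <- pk_i[i] - pk_i[last] >= min_gap
      rearm_ok <- min(dev[pk_i[last]:pk_i[i]]) < rearm
      if (gap_ok && rearm_ok) { last <- i; next }
      if (pk_a[i] > pk_a[last]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    }
    pk_i <- pk_i[keep]; pk_a <- pk_a[keep]
  }
  ev_t <- time[pk_i]
  out <- data.frame(time = ev_t, amplitude = pk_a,
                    iei = if (length(ev_t)) c(NA_real_, diff(ev_t))
                          else numeric(0))
  class(out) <- c("septodg_event_table", "data.frame")
  attr(out, "duration") <- duration
  attr(out, "noise_sd") <- noise_sd
  attr(out, "threshold_pA") <- thr
  attr(out, "frequency_hz") <- nrow(out) / duration
  out
}

#' Group statistics for sIPSC tables
#'
#' Per-cell mean amplitude and frequency compared by unpaired two-tailed
#' t-test; pooled amplitude and inter-event-interval empirical CDFs compared
#' by two-sample Kolmogorov-Smirnov test; group mean +/- SEM reported.
#'
#' @param tables list of `septodg_event_table` (one per cell).
#' @param groups group label per cell (length of `tables`).
#' @return list `per_cell` (data.frame), `comparisons` (rows from
#'   [run_comparison()]), `group_summary`.
#' @export
sipsc_group_stats <- function(tables, groups) {
  stopifnot(length(tables) == length(groups))
  if (any(table(groups) < 2))
    stop("each group needs at least 2 cells", call. = FALSE)
  per_cell <- data.frame(
    cell = seq_along(tables), group = groups,
    mean_amplitude = vapply(tables, function(tb)
      if (nrow(tb)) mean(tb$amplitude) else NA_real_, numeric(1)),
    frequency = vapply(tables, function(tb)
      attr(tb, "frequency_hz") %||% (nrow(tb) / attr(tb, "duration")),
      numeric(1)))
  comp <- rbind(
    run_comparison(data.frame(value = per_cell$mean_amplitude,
                              group = per_cell$group),
                   comparison_spec("unpaired_t", unit = "cell",
                                   measure = "mean_amplitude_pA")),
    run_comparison(data.frame(value = per_cell$frequency,
                              group = per_cell$group),
                   comparison_spec("unpaired_t", unit = "cell",
                                   measure = "frequency_hz")))
  gl <- unique(groups)
  pooled <- lapply(gl, function(g)
    do.call(rbind, tables[groups == g]))
  if (all(vapply(pooled, nrow, numeric(1)) > 0)) {
    comp <- rbind(comp,
      run_comparison(data.frame(value = c(pooled[[1]]$amplitude,
                                          pooled[[2]]$amplitude),
                                group = rep(gl, c(nrow(pooled[[1]]),
                                                  nrow(pooled[[2]])))),
                     comparison_spec("ks_two_sample", unit = "event",
                                     measure = "amplitude_cdf")),
      run_comparison(data.frame(value = c(pooled[[1]]$iei, pooled[[2]]$iei),
                                group = rep(gl, c(nrow(pooled[[1]]),
                                                  nrow(pooled[[2]])))),
                     comparison_spec("ks_two_sample", unit = "event",
                                     measure = "iei_cdf")))
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  gs <- do.call(rbind, lapply(gl, function(g) {
    sub <- per_cell[per_cell$group == g, ]
    data.frame(group = g, n_cells = nrow(sub),
               amp_mean = mean(sub$mean_amplitude), amp_sem = sem(sub$mean_amplitude),
               freq_mean = mean(sub$frequency), freq_sem = sem(sub$frequency))
  }))
  list(per_cell = per_cell, comparisons = comp, group_summary = gs)
}

# assign events/windows of one cell to pre vs light, averaged across cycles
epoch_rates <- function(tb, epochs, pre_s = NULL) {
  ev_t <- tb$time
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    s <- epochs$start[i]; e <- epochs$end[i]
    w <- e - s
    p <- pre_s %||% w
    pre_i <- ev_t >= s - p & ev_t < s      # boundary events go to light
    lit_i <- ev_t >= s & ev_t < e
    data.frame(cycle = i,
               pre_freq = sum(pre_i) / p, light_freq = sum(lit_i) / w,
               pre_amp = if (any(pre_i)) mean(tb$amplitude[pre_i]) else NA_real_,
               light_amp = if (any(lit_i)) mean(tb$amplitude[lit_i]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Paired pre-vs-light epoch comparison across cells
#'
#' For each cell, frequency and mean amplitude are computed in the pre-light
#' window (same length as the epoch, immediately preceding it) and in the
#' light window of every stimulation cycle, averaged across cycles; cells
#' are then compared by paired two-tailed t-tests.  Events exactly at an
#' epoch onset belong to the light window.
#'
#' @param tables list of `septodg_event_table`, one per cell.
#' @param epochs_list light epochs per cell (data.frame start/end), or one
#'   data.frame recycled to all cells.
#' @return list `per_cell` and `comparisons` (frequency and amplitude rows).
#' @export
opto_epoch_compare <- function(tables, epochs_list) {
  if (is.data.frame(epochs_list))
    epochs_list <- rep(list(epochs_list), length(tables))
  stopifnot(length(tables) == length(epochs_list))
  per_cell <- do.call(rbind, lapply(seq_along(tables), function(i) {
    ep <- epochs_list[[i]]
    if (is.null(ep) || nrow(ep) < 1)
      stop("at least one complete stimulation cycle required", call. = FALSE)
    er <- epoch_rates(tables[[i]], ep)
    data.frame(cell = i,
               pre_freq = mean(er$pre_freq), light_freq = mean(er$light_freq),
               pre_amp = mean(er$pre_amp, na.rm = TRUE),
               light_amp = mean(er$light_amp, na.rm = TRUE))
  }))
  comp <- rbind(
    run_comparison(data.frame(x = per_cell$pre_freq, y = per_cell$light_freq),
                   comparison_spec("paired_t", unit = "cell",
                                   measure = "frequency_pre_vs_light")),
    run_comparison(data.frame(x = per_cell$pre_amp, y = per_cell$light_amp),
                   comparison_spec("paired_t", unit = "cell",
                                   measure = "amplitude_pre_vs_light")))
  list(per_cell = per_cell, comparisons = comp)
}

# single-exponential time constant of the charging phase: log-linear
# estimate refined by nonlinear least squares (robust to additive noise)
fit_tau <- function(t, v, v0, vss) {
  y <- (v - vss) / (v0 - vss)
  ok <- is.finite(y) & y > 0.05 & y < 0.95
  if (sum(ok) < 5) return(NA_real_)
  fit <- stats::lm(log(y[ok]) ~ t[ok])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  tau0 <- -1 / slope
  refined <- tryCatch({
    nf <- suppressWarnings(
      stats::nls(v ~ b + a * exp(-t / tau),
                 start = list(b = vss, a = v0 - vss, tau = tau0),
                 control = stats::nls.control(warnOnly = TRUE)))
    cf <- stats::coef(nf)
    if (cf[["tau"]] > 0) cf[["tau"]] else tau0
  }, error = function(e) tau0)
  refined
}

# upward 0 mV crossings with a refractory gap, s
count_spikes <- function(v, time, thresh_mV = 0, refractory_ms = 2) {
  up <- which(v[-1] >= thresh_mV & v[-length(v)] < thresh_mV) + 1L
  if (!length(up)) return(numeric(0))
  dt_min <- refractory_ms / 1000
  keep <- c(TRUE, diff(time[up]) >= dt_min)
  time[up][keep]
}

#' Intrinsic membrane properties from current-clamp protocols
#'
#' RMP is the mean pre-step voltage of the zero-current ladder sweep; input
#' resistance is `dV_ss / dI` from the -20 pA, 200 ms pulse with the steady
#' state taken over the last 25% (50 ms) of the pulse; the membrane time
#' constant comes from a single-exponential fit of the charging phase;
#' capacitance is `tau / R`.  AP threshold is the voltage where dV/dt first
#' exceeds 20 mV/ms before the first spike.  The F-I table counts spikes
#' (upward 0 mV crossings, 2 ms refractory) in each 500 ms step.
#'
#' @param sweeps a `septodg_sweepset` from [simulate_current_steps()] or a
#'   compatible structure.
#' @return a `septodg_intrinsic` list: `rmp_mV`, `rin_Mohm`, `tau_ms`,
#'   `capacitance_pF`, `ap_threshold_mV`, `rheobase_pA`, `fi` (data.frame
#'   current_pA, spikes).
#' @export
intrinsic_properties <- function(sweeps) {
  if (is.null(sweeps$rin) || is.null(sweeps$steps))
    stop("protocol metadata (rin pulse + step ladder) required", call. = FALSE)
  fs <- sweeps$fs
  r <- sweeps$rin
  on <- r$pulse[1]; off <- r$pulse[2]
  pre <- r$v[r$time < on]
  v_pre <- mean(pre)
  ss_idx <- r$time >= off - 0.25 * (off - on) & r$time < off
  v_ss <- mean(r$v[ss_idx])
  dv <- v_ss - v_pre                            # mV
  rin <- dv / (r$I_pA * 1e-3)                   # MOhm
  chg <- r$time >= on & r$time < off
  tau_s <- fit_tau(r$time[chg] - on, r$v[chg], v0 = v_pre, vss = v_ss)
  tau_ms <- if (is.finite(tau_s)) tau_s * 1000 else NA_real_
  cap_pF <- if (is.finite(tau_ms) && rin > 0) tau_ms / rin * 1000 else NA_real_

  win <- sweeps$step_window
  fi <- do.call(rbind, lapply(sweeps$steps, function(s) {
    st <- count_spikes(s$v, s$time)
    st <- st[st >= win[1] & st < win[2]]
    data.frame(current_pA = s$I_pA, spikes = length(st))
  }))
  rmp_sweep <- Filter(function(s) s$I_pA == 0, sweeps$steps)
  rmp <- if (length(rmp_sweep))
    mean(rmp_sweep[[1]]$v[rmp_sweep[[1]]$time < win[1]]) else v_pre

  firing <- fi$current_pA[fi$spikes > 0]
  rheo <- if (length(firing)) min(firing) else NA_real_
  ap_thr <- NA_real_
  if (is.finite(rheo)) {
    s1 <- Filter(function(s) s$I_pA == rheo, sweeps$steps)[[1]]
    first_spk <- count_spikes(s1$v, s1$time)[1]
    seg <- s1$time < first_spk
    dvdt <- c(0, diff(s1$v[seg])) * fs / 1000    # mV/ms
    hit <- which(dvdt > 20)[1]
    # the voltage just before the fast upstroke begins
    if (!is.na(hit) && hit > 1) ap_thr <- s1$v[seg][hit - 1]
  }
  structure(list(rmp_mV = rmp, rin_Mohm = rin, tau_ms = tau_ms,
                 capacitance_pF = cap_pF, ap_threshold_mV = ap_thr,
                 rheobase_pA = rheo, fi = fi),
            class = "septodg_intrinsic")
}

#' Two-way genotype x current comparison of F-I tables
#'
#' Two-way ANOVA (Type II sums of squares, suited to unbalanced cell counts)
#' with factors genotype and injected current on per-step spike counts.
#' Steps missing from any cell are excluded listwise.
#'
#' @param fi_tables list of F-I data.frames (current_pA, spikes), one per
#'   cell.
#' @param groups genotype label per cell.
#' @return data.frame of effect rows (effect, df, F, p, sig).
#' @export
fi_group_compare <- function(fi_tables, groups) {
  stopifnot(length(fi_tables) == length(groups))
  long <- do.call(rbind, lapply(seq_along(fi_tables), function(i)
    cbind(fi_tables[[i]], cell = i, genotype = groups[i])))
  common <- Reduce(intersect, lapply(fi_tables, function(tb) tb$current_pA))
  dropped <- setdiff(unique(long$current_pA), common)
  if (length(dropped))
    message("excluding current steps missing in some cells: ",
            paste(dropped, collapse = ", "))
  long <- long[long$current_pA %in% common, ]
  if (length(common) < 2)
    stop("degenerate design: need at least 2 common current levels",
         call. = FALSE)
  res <- anova_type2(long$spikes, factor(long$genotype),
                     factor(long$current_pA),
                     names = c("genotype", "current", "genotype:current"))
  res
}
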