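# Synthetic slice-electrophysiology recordings (10 kHz).

#' Default optogenetic light protocol
#'
#' 20-s light epochs delivered once per 60-s cycle (light on 20 s into each
#' cycle), the stimulation layout the opto-epoch contrast assumes.
#'
#' @param duration_s trace duration, s.
#' @param cycle_s cycle length, s (default 60).
#' @param epoch_s light epoch length, s (default 20).
#' @param onset_s light onset within each cycle, s (default 20, leaving a
#'   20-s pre-light window).
#' @return data.frame (start, end) in s.
#' @export
light_protocol <- function(duration_s, cycle_s = 60, epoch_s = 20,
                           onset_s = 20) {
  starts <- seq(onset_s, duration_s - epoch_s, by = cycle_s)
  data.frame(start = starts, end = starts + epoch_s)
}

validate_epochs <- function(epochs, duration_s) {
  if (is.null(epochs) || nrow(epochs) == 0) return(invisible(NULL))
  if (any(epochs$start < 0) || any(epochs$end > duration_s))
    stop("light epoch outside the trace", call. = FALSE)
  if (any(epochs$end <= epochs$start))
    stop("light epochs must have positive length", call. = FALSE)
  o <- order(epochs$start)
  if (nrow(epochs) > 1 &&
      any(epochs$start[o][-1] < epochs$end[o][-nrow(epochs)]))
    stop("overlapping light epochs", call. = FALSE)
  invisible(NULL)
}

# unit-peak biexponential synaptic kernel, times in s
sipsc_kernel <- function(t, rise_s, decay_s) {
  k <- ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  t_pk <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  k / (exp(-t_pk / decay_s) - exp(-t_pk / rise_s))
}

#' Simulate a voltage-clamp sIPSC trace
#'
#' Spontaneous inhibitory currents at -65 mV holding with a CsCl internal:
#' events are inward (downward) deflections with biexponential kinetics
#' (rise ~0.5 ms, decay ~8 ms) and lognormal peak amplitudes, on a Poisson
#' train.  Inside light epochs the event rate and/or amplitude is multiplied
#' by `cfg$ephys$opto_mod` (a factor < 1 models reduced inhibitory drive).
#' Amplitudes are reported as positive magnitudes throughout.
#'
#' @param cfg a [sim_config()].
#' @param duration_s trace length, s (default 60).
#' @param light optional epoch data.frame (start, end); `NULL` for none.
#' @param mod_target which statistic the light modulates: `"frequency"`,
#'   `"amplitude"`, or `"both"`.
#' @param event_times optional scripted event times (s) overriding the
#'   Poisson train (light modulation then applies to amplitude only).
#' @param cell cell identifier.
#' @param seed optional.
#' @return `list(sweeps, truth)`: a `septodg_sweepset` (single voltage-clamp
#'   trace, pA) and ground truth (`event_times` s, `event_amps` pA).
#' @export
simulate_sipsc_trace <- function(cfg, duration_s = 60, light = NULL,
                                 mod_target = "frequency",
                                 event_times = NULL, cell = "c1",
                                 seed = NULL) {
  e <- cfg$ephys
  stopifnot(e$sipsc_rate >= 0, duration_s > 0)
  validate_epochs(light, duration_s)
  seed <- seed %||% child_seed(cfg$seed, paste("sipsc", cell, sep = "/"))
  set.seed(seed)

  fs <- e$fs
  time <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  mod <- e$opto_mod
  in_light <- function(tt) {
    if (is.null(light) || nrow(light) == 0) return(rep(FALSE, length(tt)))
    vapply(tt, function(x) any(x >= light$start & x < light$end), logical(1))
  }
  if (is.null(event_times)) {
    # thinning for rate modulation inside light epochs
    rmax <- e$sipsc_rate * max(1, if (mod_target != "amplitude") mod else 1)
    n_cand <- stats::rpois(1, rmax * duration_s)
    cand <- sort(stats::runif(n_cand, 0, duration_s))
    if (length(cand)) {
      lit <- in_light(cand)
      r_loc <- e$sipsc_rate *
        ifelse(lit & mod_target %in% c("frequency", "both"), mod, 1)
      cand <- cand[stats::runif(length(cand)) < r_loc / rmax]
    }
    ev_t <- cand
  } else {
    stopifnot(all(event_times >= 0), all(event_times < duration_s))
    ev_t <- sort(event_times)
  }
  ev_a <- stats::rlnorm(length(ev_t), e$amp_meanlog, e$amp_sdlog)
  if (length(ev_t) && mod_target %in% c("amplitude", "both"))
    ev_a <- ev_a * ifelse(in_light(ev_t), mod, 1)

  x <- rep(e$baseline_pA, length(time))
  if (length(ev_t)) {
    rise <- e$rise_ms / 1000; decay <- e$decay_ms / 1000
    span <- ceiling((rise + 8 * decay) * fs)
    for (i in seq_along(ev_t)) {
      j0 <- floor(ev_t[i] * fs) + 1L
      idx <- j0:min(length(time), j0 + span)
      x[idx] <- x[idx] - ev_a[i] * sipsc_kernel(time[idx] - ev_t[i], rise, decay)
    }
  }
  x <- x + stats::rnorm(length(x), 0, e$noise_sd_pA)

  sweeps <- structure(list(
    traces = list(data.frame(time = time, signal = x)),
    fs = fs, mode = "voltage_clamp", holding_mV = -65,
    light_epochs = light, duration_s = duration_s, cell = cell,
    ra_checkpoints = c(start = 12, end = 12)
  ), class = "septodg_sweepset")
  truth <- list(event_times = ev_t, event_amps = ev_a, seed = seed,
                rate_hz = e$sipsc_rate, mod = mod, mod_target = mod_target)
  list(sweeps = sweeps, truth = truth)
}

# Euler leaky-integrate-and-fire with stereotyped spikes
lif_trace <- function(time, I_pA, rmp, R, tau_s, v_th, fs, noise_sd = 0) {
  n <- length(time)
  v <- numeric(n); v[1] <- rmp
  dt <- 1 / fs
  spike_t <- numeric(0)
  refr <- 0L
  ramp_n <- max(2L, round(0.0003 * fs))     # 0.3 ms fast upstroke
  spike_hold <- round(0.0005 * fs)          # 0.5 ms at +30 mV crest
  refr_n <- round(0.002 * fs)               # 2 ms refractory
  i <- 2L
  while (i <= n) {
    if (refr > 0L) { v[i] <- rmp; refr <- refr - 1L; i <- i + 1L; next }
    dv <- (-(v[i - 1L] - rmp) + I_pA[i] * R * 1e-3) * dt / tau_s
    v[i] <- v[i - 1L] + dv + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
    if (v[i] >= v_th) {
      spike_t <- c(spike_t, time[i])
      up <- i + seq_len(ramp_n)              # stereotyped AP upstroke + crest
      up <- up[up <= n]
      v[up] <- v[i] + (30 - v[i]) * seq_along(up) / ramp_n
      hold <- (i + ramp_n + 1L):min(n, i + ramp_n + spike_hold)
      if (length(hold) && hold[1] <= n) v[hold[hold <= n]] <- 30
      i <- min(n, i + ramp_n + spike_hold) + 1L
      refr <- refr_n
      next
    }
    i <- i + 1L
  }
  list(v = v, spike_times = spike_t)
}

#' Simulate current-clamp step protocols
#'
#' Two protocols from one RC + leaky-integrate-and-fire cell:
#' a hyperpolarizing input-resistance pulse (-20 pA, 200 ms), and the F-I
#' ladder of 16 current steps (500 ms) from -20 to +280 pA in 20 pA
#' increments.  Passive response follows `V(t) = RMP + I R (1 - e^(-t/tau))`;
#' spikes fire when V crosses a threshold placed midway between the last
#' subthreshold and first suprathreshold ladder step, so the ground-truth
#' rheobase is exactly `cfg$ephys$rheobase_pA` on the 20 pA grid.
#'
#' @param cfg a [sim_config()].
#' @param cell cell identifier.
#' @param seed optional.
#' @return `list(sweeps, truth)`; `sweeps$rin` holds the -20 pA pulse sweep
#'   (`time`, `v`, `pulse` on/off s), `sweeps$steps` the ladder sweeps, each
#'   `list(I_pA, time, v, spike_times)`, with `step_window` (on, off) s.
#' @export
simulate_current_steps <- function(cfg, cell = "c1", seed = NULL) {
  e <- cfg$ephys
  stopifnot(e$R_Mohm > 0, e$tau_ms > 0)
  seed <- seed %||% child_seed(cfg$seed, paste("steps", cell, sep = "/"))
  set.seed(seed)
  fs <- e$fs
  tau <- e$tau_ms / 1000
  rmp <- e$rmp_mV
  R <- e$R_Mohm
  # threshold between (rheobase - 20) and rheobase steady-state depolarisations
  v_th <- rmp + (e$rheobase_pA - 10) * R * 1e-3

  # input-resistance pulse: 100 ms pre, 200 ms at -20 pA, 200 ms post
  t_r <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
  on <- 0.1; off <- 0.3
  vr <- rmp +
    ifelse(t_r >= on & t_r < off,
           -20 * R * 1e-3 * (1 - exp(-(t_r - on) / tau)),
           ifelse(t_r >= off,
                  -20 * R * 1e-3 * (1 - exp(-(off - on) / tau)) *
                    exp(-(t_r - off) / tau), 0))
  if (e$noise_sd_mV > 0) vr <- vr + stats::rnorm(length(vr), 0, e$noise_sd_mV)
  rin <- list(time = t_r, v = vr, I_pA = -20, pulse = c(on, off))

  # F-I ladder: 100 ms pre, 500 ms step, 100 ms post
  t_s <- seq(0, 0.7 - 1 / fs, by = 1 / fs)
  s_on <- 0.1; s_off <- 0.6
  ladder <- seq(-20, 280, by = 20)
  steps <- lapply(ladder, function(I) {
    Ivec <- ifelse(t_s >= s_on & t_s < s_off, I, 0)
    lf <- lif_trace(t_s, Ivec, rmp, R, tau, v_th, fs, e$noise_sd_mV)
    list(I_pA = I, time = t_s, v = lf$v, spike_times = lf$spike_times)
  })

  sweeps <- structure(list(
    rin = rin, steps = steps, step_window = c(s_on, s_off),
    fs = fs, mode = "current_clamp", cell = cell,
    ra_checkpoints = c(start = 12, end = 12)
  ), class = "septodg_sweepset")
  # smallest ladder step whose steady-state depolarisation clears threshold
  rheo_step <- ladder[ladder * R * 1e-3 > (v_th - rmp) + 1e-9][1]
  truth <- list(R_Mohm = R, tau_ms = e$tau_ms, C_pF = e$tau_ms / R * 1000,
                rmp_mV = rmp, rheobase_pA = e$rheobase_pA,
                rheobase_step_pA = rheo_step, v_th = v_th,
                spike_counts = vapply(steps, function(s)
                  length(s$spike_times), numeric(1)),
                ladder = ladder, seed = seed)
  list(sweeps = sweeps, truth = truth)
}
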