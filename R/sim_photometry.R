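# Synthetic fiber-photometry sessions with known ground truth.

#' Calcium transient kernel
#'
#' Double-exponential kernel `exp(-t/decay) - exp(-t/rise)` normalised to a
#' peak of 1, the standard GCaMP6f-like approximation (rise ~0.1 s, decay
#' ~0.4 s by default).
#'
#' @param t time since event onset, s (vector; values < 0 give 0).
#' @param rise_s,decay_s kinetics, s; `decay_s > rise_s` required.
#' @return kernel values, unit peak.
#' @export
transient_kernel <- function(t, rise_s = 0.1, decay_s = 0.4) {
  stopifnot(decay_s > rise_s, rise_s > 0)
  k <- ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  t_peak <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  k / (exp(-t_peak / decay_s) - exp(-t_peak / rise_s))
}

# superpose unit-peak transients (amplitudes in dF/F) on a time grid
superpose_transients <- function(time, onsets, amps, rise_s, decay_s) {
  out <- numeric(length(time))
  if (length(onsets) == 0) return(out)
  dt <- time[2] - time[1]
  span <- ceiling((rise_s + 8 * decay_s) / dt)
  for (i in seq_along(onsets)) {
    j0 <- findInterval(onsets[i], time)
    idx <- max(1L, j0):min(length(time), j0 + span)
    out[idx] <- out[idx] +
      amps[i] * transient_kernel(time[idx] - onsets[i], rise_s, decay_s)
  }
  out
}

# shared low-frequency motion waveform (a.u.), ~1 s autocorrelation
motion_waveform <- function(n, fs, amp) {
  if (amp == 0) return(numeric(n))
  w <- as.numeric(stats::filter(stats::rnorm(n + 2L * fs), rep(1, fs) / fs,
                                sides = 2))
  w <- w[(fs + 1L):(fs + n)]
  w[is.na(w)] <- 0
  amp * w / max(stats::sd(w), .Machine$double.eps)
}

#' Simulate one fiber-photometry session
#'
#' Produces a dual-channel (GCaMP + mCherry) session at `fs_photo`.  The
#' GCaMP channel is `baseline * (1 + drift) * (1 + sum of transients)` plus a
#' shared motion artifact and Gaussian noise; the mCherry channel carries the
#' *same* motion waveform plus independent noise but no transients, which is
#' what makes regression-based motion control work downstream.  Event times
#' are Poisson at the genotype's rate; when a behavior track is attached the
#' rate is multiplied by `bout_gain` inside exploration bouts.
#'
#' @param cfg a [sim_config()] object.
#' @param genotype name into `cfg$genotype_params` (e.g. `"WT"`).
#' @param site recording site label, `"DG"` or `"MS"`.
#' @param context `"homecage"` or `"arena"`.
#' @param track optional behavior track from [simulate_behavior_track()];
#'   its scripted bouts modulate the event rate and set the session length.
#' @param events optional data.frame `(time, amp)` of extra scripted
#'   transients (used for bout-locked paired sessions).
#' @param background_rate override of the genotype event rate, events/min.
#' @param animal animal identifier.
#' @param seed optional; defaults to a [child_seed()] of `cfg$seed`.
#' @return `list(session, truth)`: a `septodg_photometry_session` and a
#'   ground-truth list with `event_times` (s) and `event_amps` (peak dF/F).
#' @export
simulate_photometry_session <- function(cfg, genotype = "WT", site = "DG",
                                        context = "homecage", track = NULL,
                                        events = NULL, background_rate = NULL,
                                        animal = "a1", seed = NULL) {
  p <- cfg$photometry
  stop_if_not_scalar_pos(p$duration_s, "duration_s")
  if (p$duration_s < 60) stop("duration must be at least 60 s", call. = FALSE)
  duration <- if (!is.null(track)) max(track$time) else p$duration_s
  seed <- seed %||% child_seed(cfg$seed, paste("photo", genotype, site, animal,
                                               context, sep = "/"))
  set.seed(seed)

  fs <- p$fs_photo
  time <- seq(0, duration, by = 1 / fs)
  n <- length(time)
  rate_min <- background_rate %||% cfg$genotype_params[[genotype]]$event_rate
  amp0 <- cfg$genotype_params[[genotype]]$amplitude

  # Poisson background events, thinned to implement bout-gain modulation
  g <- if (!is.null(track)) max(1, p$bout_gain) else 1
  lambda_hz <- rate_min / 60
  n_cand <- stats::rpois(1, lambda_hz * g * duration)
  cand <- sort(stats::runif(n_cand, 0, duration))
  if (!is.null(track) && length(cand)) {
    in_bout <- vapply(cand, function(tt)
      any(tt >= track$bouts$onset & tt < track$bouts$offset), logical(1))
    keep_p <- ifelse(in_bout, p$bout_gain / g, 1 / g)
    cand <- cand[stats::runif(length(cand)) < keep_p]
  } else if (g != 1) {
    cand <- cand[stats::runif(length(cand)) < 1 / g]
  }
  ev_t <- cand
  ev_a <- if (length(ev_t)) amp0 * exp(stats::rnorm(length(ev_t), 0, 0.2)) else numeric(0)
  if (!is.null(events) && nrow(events)) {
    ev_t <- c(ev_t, events$time)
    ev_a <- c(ev_a, events$amp)
    o <- order(ev_t); ev_t <- ev_t[o]; ev_a <- ev_a[o]
  }

  dff_true <- superpose_transients(time, ev_t, ev_a, p$rise_s, p$decay_s)
  drift <- p$drift_amp * sin(2 * pi * time / duration + stats::runif(1, 0, 2 * pi))
  motion <- motion_waveform(n, fs, p$motion_amp)
  f_g <- p$baseline * (1 + drift) * (1 + dff_true) + motion +
    stats::rnorm(n, 0, p$noise_sd * p$baseline)
  f_m <- 0.8 * p$baseline + motion +
    stats::rnorm(n, 0, p$noise_sd * p$baseline * 0.5)
  f_g <- pmax(f_g, 0); f_m <- pmax(f_m, 0)

  session <- structure(list(
    time = time, F_gcamp = f_g, F_mcherry = f_m,
    site = site, animal = animal, genotype = genotype, context = context,
    fs = fs
  ), class = "septodg_photometry_session")
  truth <- list(event_times = ev_t, event_amps = ev_a, seed = seed,
                rate_per_min = rate_min, motion = motion)
  list(session = session, truth = truth)
}

#' Simulate paired DG + MS sessions with correlated bout responses
#'
#' Emulates simultaneous dual-site recording during a novel-place-recognition
#' phase.  Calcium activity is elevated *throughout* each scripted bout
#' (transients at `intra_bout_gap_s` spacing from onset to offset), matching
#' peri-event averages that stay raised across exploration; all transients
#' of one bout share that bout's amplitude.  The per-bout (DG, MS)
#' amplitude pairs are bivariate normal with correlation `rho`, so the
#' downstream bout-response Pearson r has a known target.  Encoding-phase
#' defaults use the genotype's `coupling`; pass `rho = 0` to emulate the
#' retrieval-phase decoupling.
#'
#' @param cfg a [sim_config()].
#' @param track behavior track providing scripted bouts.
#' @param rho target amplitude correlation in `[-1, 1]`; defaults to the
#'   genotype's `coupling`.
#' @param amp_cv coefficient of variation of bout amplitudes (default 0.3).
#' @param intra_bout_gap_s spacing of transients within a bout, s
#'   (default 1).
#' @param genotype,animal,seed as in [simulate_photometry_session()].
#' @param background_rate background event rate, events/min (default 0:
#'   bout-locked activity only, the regime the coupling analysis targets).
#' @return list with `dg`, `ms` (each a `list(session, truth)`) and
#'   `bout_amps` data.frame (bout, dg_amp, ms_amp).
#' @export
simulate_paired_sessions <- function(cfg, track, rho = NULL, genotype = "WT",
                                     amp_cv = 0.3, background_rate = 0,
                                     intra_bout_gap_s = 1,
                                     animal = "a1", seed = NULL) {
  rho <- rho %||% cfg$genotype_params[[genotype]]$coupling
  stopifnot(abs(rho) <= 1)
  seed <- seed %||% child_seed(cfg$seed, paste("paired", genotype, animal, sep = "/"))
  set.seed(seed)
  nb <- nrow(track$bouts)
  if (nb == 0) stop("track has no scripted bouts", call. = FALSE)
  amp0 <- cfg$genotype_params[[genotype]]$amplitude
  # bivariate normal amplitude pairs; the positivity floor binds only
  # beyond ~3 SD, so cor(a_dg, a_ms) stays at rho to within Monte-Carlo
  # tolerance (heavier-tailed choices inflate the sampling variance of r)
  z1 <- stats::rnorm(nb)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(nb)
  a_dg <- pmax(amp0 * (1 + amp_cv * z1), 0.05 * amp0)
  a_ms <- pmax(amp0 * (1 + amp_cv * z2), 0.05 * amp0)
  # sustained in-bout activity: one transient every intra_bout_gap_s,
  # all carrying the bout's amplitude
  ev_bout <- lapply(seq_len(nb), function(i)
    track$bouts$onset[i] +
      seq(0, max(track$bouts$duration[i] - 0.5, 0), by = intra_bout_gap_s))
  n_sub <- lengths(ev_bout)
  ev_dg <- data.frame(time = unlist(ev_bout), amp = rep(a_dg, n_sub))
  ev_ms <- data.frame(time = unlist(ev_bout), amp = rep(a_ms, n_sub))
  dg <- simulate_photometry_session(cfg, genotype, "DG", "arena", track,
                                    events = ev_dg,
                                    background_rate = background_rate,
                                    animal = animal,
                                    seed = child_seed(seed, "dg"))
  ms <- simulate_photometry_session(cfg, genotype, "MS", "arena", track,
                                    events = ev_ms,
                                    background_rate = background_rate,
                                    animal = animal,
                                    seed = child_seed(seed, "ms"))
  list(dg = dg, ms = ms,
       bout_amps = data.frame(bout = seq_len(nb), dg_amp = a_dg, ms_amp = a_ms),
       rho = rho)
}

#' Synthetic per-timepoint emission spectra for a photometry session
#'
#' Optional spectrometer-style mode: renders each timepoint of a session as
#' an emission spectrum with Gaussian GCaMP (peak 515 nm) and mCherry (peak
#' 610 nm) bands whose integrated band power equals the channel fluorescence.
#'
#' @param session a `septodg_photometry_session`.
#' @param wavelengths nm grid (default 480-650 nm at 1 nm).
#' @return matrix timepoints x wavelengths, with attribute `"wavelengths"`.
#' @export
render_emission_spectra <- function(session,
                                    wavelengths = seq(480, 650, by = 1)) {
  g_shape <- stats::dnorm(wavelengths, 515, 10)
  m_shape <- stats::dnorm(wavelengths, 610, 12)
  # normalise so integral over the standard bands returns channel F
  dl <- mean(diff(wavelengths))
  g_band <- wavelengths >= 500 & wavelengths <= 540
  m_band <- wavelengths >= 580 & wavelengths <= 620
  g_shape <- g_shape / (sum(g_shape[g_band]) * dl)
  m_shape <- m_shape / (sum(m_shape[m_band]) * dl)
  sp <- outer(session$F_gcamp, g_shape) + outer(session$F_mcherry, m_shape)
  attr(sp, "wavelengths") <- wavelengths
  sp
}
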