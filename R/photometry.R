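# dF/F computation, motion control, and calcium-event detection.

#' Integrate emission spectra into channel fluorescence
#'
#' Per-timepoint channel fluorescence is the integral of the emission
#' spectrum over a configured wavelength band (defaults: 500-540 nm for
#' GCaMP, 580-620 nm for mCherry), matching spectrometer-based acquisition
#' where each channel is read off one emission band.
#'
#' @param spectra matrix timepoints x wavelengths with a `"wavelengths"`
#'   attribute, or with `wavelengths` supplied explicitly.
#' @param wavelengths nm grid (one per spectrum column).
#' @param gcamp_band,mcherry_band numeric length-2 band limits, nm.
#' @return list `F_gcamp`, `F_mcherry` (a.u., trapezoid-free simple sum
#'   times the wavelength step).
#' @export
extract_channels <- function(spectra, wavelengths = attr(spectra, "wavelengths"),
                             gcamp_band = c(500, 540),
                             mcherry_band = c(580, 620)) {
  if (is.null(wavelengths)) stop("wavelength grid required", call. = FALSE)
  rng <- range(wavelengths)
  for (b in list(gcamp_band, mcherry_band))
    if (b[1] < rng[1] || b[2] > rng[2])
      stop("integration band outside the wavelength grid", call. = FALSE)
  dl <- mean(diff(wavelengths))
  gi <- wavelengths >= gcamp_band[1] & wavelengths <= gcamp_band[2]
  mi <- wavelengths >= mcherry_band[1] & wavelengths <= mcherry_band[2]
  list(F_gcamp = as.numeric(spectra[, gi, drop = FALSE] %*% rep(dl, sum(gi))),
       F_mcherry = as.numeric(spectra[, mi, drop = FALSE] %*% rep(dl, sum(mi))))
}

#' Compute dF/F from raw fluorescence
#'
#' `dff = (F - F0) / F0` with `F0` the median of the whole-session
#' fluorescence.  The event threshold is `3 * SD(dff)` (sample SD over the
#' full session).  Both choices make the trace, and everything downstream,
#' invariant under multiplicative rescaling of raw fluorescence.
#'
#' @param F numeric fluorescence series (a.u.), at least 2 samples.
#' @param time optional time base, s.
#' @param k_sd threshold multiplier (default 3).
#' @return a `septodg_dff` list: `time`, `dff`, `F0`, `sd`, `threshold`.
#' @export
compute_dff <- function(F, time = NULL, k_sd = 3) {
  if (length(F) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(F)) || any(F < 0))
    stop("fluorescence must be finite and non-negative", call. = FALSE)
  F0 <- stats::median(F)
  if (F0 <= 0) stop("non-positive median fluorescence: degenerate input",
                    call. = FALSE)
  dff <- (F - F0) / F0
  s <- stats::sd(dff)
  structure(list(time = time %||% seq_along(F), dff = dff, F0 = F0,
                 sd = s, threshold = k_sd * s, k_sd = k_sd),
            class = "septodg_dff")
}

#' Motion control by mCherry regression
#'
#' The activity-independent mCherry channel carries the same motion artifact
#' as the GCaMP channel.  An ordinary least-squares fit
#' `dff_gcamp ~ a * dff_mcherry + b` is used to subtract the
#' mCherry-predicted component; the corrected trace has (numerically) zero
#' sample correlation with the regressor.  The threshold is recomputed
#' on the corrected trace.  A zero-variance mCherry trace skips the
#' correction with a warning.
#'
#' Because motion artifacts are slow relative to shot noise, regressing on
#' the raw control channel attenuates the fitted slope (errors in
#' variables) and under-corrects.  `smooth_s > 0` applies a moving-average
#' of that width to the mCherry regressor first; the default 0 keeps the
#' plain OLS contract, and [analyze_photometry_session()] uses 1 s.
#'
#' @param dff_gcamp,dff_mcherry `septodg_dff` objects on the same time base.
#' @param enabled set `FALSE` to pass the GCaMP trace through untouched.
#' @param smooth_s moving-average width applied to the mCherry regressor,
#'   s (default 0 = none).
#' @return a `septodg_dff` with extra fields `a`, `b` (fit coefficients)
#'   and `corrected` flag.
#' @export
motion_correct <- function(dff_gcamp, dff_mcherry, enabled = TRUE,
                           smooth_s = 0) {
  if (length(dff_gcamp$dff) != length(dff_mcherry$dff))
    stop("traces must have equal length", call. = FALSE)
  if (!enabled) {
    dff_gcamp$corrected <- FALSE
    return(dff_gcamp)
  }
  x <- dff_mcherry$dff; y <- dff_gcamp$dff
  if (smooth_s > 0) {
    dt <- stats::median(diff(dff_mcherry$time))
    w <- max(1L, round(smooth_s / dt)); if (w %% 2 == 0) w <- w + 1L
    pad <- (w - 1L) %/% 2L
    xp <- c(rev(x[seq_len(pad)]), x, rev(x[length(x) - seq_len(pad) + 1]))
    x <- as.numeric(stats::filter(xp, rep(1 / w, w),
                                  sides = 2))[(pad + 1):(pad + length(x))]
  }
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    warning("zero-variance mCherry trace: motion correction skipped")
    dff_gcamp$corrected <- FALSE
    return(dff_gcamp)
  }
  a <- stats::cov(x, y) / stats::var(x)
  b <- mean(y) - a * mean(x)
  corr <- y - a * x
  out <- dff_gcamp
  out$dff <- corr
  out$sd <- stats::sd(corr)
  out$threshold <- (dff_gcamp$k_sd %||% 3) * out$sd
  out$a <- a; out$b <- b; out$corrected <- TRUE
  out
}

#' Detect calcium activity events on a dF/F trace
#'
#' Maximal contiguous runs of samples with `dff > threshold` become events;
#' runs separated by a gap shorter than `min_gap_s` are merged first (a
#' transient with ~0.4 s decay cannot terminate and re-initiate within
#' 200 ms, so such dips are noise), then runs shorter than `min_dur_s` are
#' discarded.  The suprathreshold area
#' `AUC = sum((dff - threshold)^+ * dt)` and the suprathreshold time
#' fraction are reported alongside count and rate.
#'
#' @param dff a `septodg_dff` (threshold computed on this same trace).
#' @param min_dur_s minimum event duration, s (default 0.2 = 2 samples at
#'   10 Hz).
#' @param min_gap_s sub-threshold gaps shorter than this merge adjacent
#'   runs (default 0.2 s; 0 disables merging).
#' @param threshold override the trace's stored threshold.
#' @return a `septodg_events` list: `onsets`, `offsets` (s), `peaks`
#'   (dF/F), `count`, `rate_per_min`, `auc` (dF/F s), `suprathreshold_frac`,
#'   `duration_s`, `threshold`.
#' @export
detect_events <- function(dff, min_dur_s = 0.2, min_gap_s = 0.2,
                          threshold = NULL) {
  if (length(dff$dff) == 0) stop("empty trace", call. = FALSE)
  thr <- threshold %||% dff$threshold
  t <- dff$time
  dt <- if (length(t) > 1) stats::median(diff(t)) else 1
  above <- dff$dff > thr
  rr <- runs_true(above)
  if (nrow(rr) > 1 && min_gap_s > 0) {
    gap_n <- min_gap_s / dt
    keep_sep <- c(TRUE, (rr$start[-1] - rr$end[-nrow(rr)] - 1L) >= gap_n)
    grp <- cumsum(keep_sep)
    rr <- data.frame(start = tapply(rr$start, grp, min),
                     end = tapply(rr$end, grp, max))
  }
  if (nrow(rr)) {
    dur <- (rr$end - rr$start + 1L) * dt
    rr <- rr[dur >= min_dur_s - 1e-9, , drop = FALSE]
  }
  onsets <- t[rr$start]
  offsets <- t[rr$end] + dt
  peaks <- if (nrow(rr)) vapply(seq_len(nrow(rr)), function(i)
    max(dff$dff[rr$start[i]:rr$end[i]]), numeric(1)) else numeric(0)
  duration <- length(t) * dt
  structure(list(
    onsets = onsets, offsets = offsets, peaks = peaks,
    count = length(onsets),
    rate_per_min = length(onsets) / duration * 60,
    auc = sum(pmax(dff$dff - thr, 0)) * dt,
    suprathreshold_frac = mean(above),
    duration_s = duration, threshold = thr
  ), class = "septodg_events")
}

#' Per-session calcium activity summary
#'
#' The per-animal scalar(s) used for group comparison: event rate
#' (events/min) and cumulative suprathreshold area; both are carried so
#' group contrasts can be run on either readout.
#'
#' @param events a `septodg_events`.
#' @param duration_s session duration, s (defaults to the events' value).
#' @return data.frame with `rate_per_min`, `auc`, `count`,
#'   `suprathreshold_frac`.
#' @export
session_activity <- function(events, duration_s = NULL) {
  duration_s <- duration_s %||% events$duration_s
  stop_if_not_scalar_pos(duration_s, "duration_s")
  data.frame(rate_per_min = events$count / duration_s * 60,
             auc = events$auc, count = events$count,
             suprathreshold_frac = events$suprathreshold_frac)
}

#' Full single-session photometry analysis
#'
#' Convenience wrapper: dF/F on both channels, optional motion correction,
#' event detection, activity summary.
#'
#' @param session a `septodg_photometry_session`.
#' @param motion_correct apply mCherry regression control (default TRUE).
#' @param min_dur_s minimum event duration, s.
#' @param mcherry_smooth_s regressor smoothing passed to
#'   [motion_correct()] (default 1 s).
#' @return list `dff`, `events`, `activity`.
#' @export
analyze_photometry_session <- function(session, motion_correct = TRUE,
                                       min_dur_s = 0.2,
                                       mcherry_smooth_s = 1) {
  dg <- compute_dff(session$F_gcamp, session$time)
  if (motion_correct) {
    dm <- compute_dff(session$F_mcherry, session$time)
    dg <- motion_correct(dg, dm, smooth_s = mcherry_smooth_s)
  }
  ev <- detect_events(dg, min_dur_s = min_dur_s)
  list(dff = dg, events = ev, activity = session_activity(ev))
}
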