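# Peri-event time-locking of dF/F to exploration bouts, and MS-DG coupling.

#' Align a 10 Hz photometry trace with a 20 Hz behavior track
#'
#' Snaps bout boundaries onto the photometry sample grid (nearest sample,
#' maximum error half a photometry sample = 50 ms at 10 Hz) and downsamples
#' the behavior channels onto the photometry timestamps by nearest video
#' frame.
#'
#' @param dff a `septodg_dff` at the photometry rate.
#' @param track a `septodg_behavior_track` (20 Hz).
#' @param bouts bout table; defaults to the track's scripted/detected bouts.
#' @return list: `dff`, `bouts` (snapped onset/offset), `behavior`
#'   (data.frame time, x, y, dir_deg at photometry timestamps).
#' @export
align_timebases <- function(dff, track, bouts = track$bouts) {
  t_p <- dff$time
  if (max(track$time) < min(t_p) || min(track$time) > max(t_p))
    stop("photometry and behavior recordings do not overlap", call. = FALSE)
  snap <- function(v) t_p[pmin(pmax(round(stats::approx(
    t_p, seq_along(t_p), xout = v, rule = 2)$y), 1), length(t_p))]
  bouts$onset_raw <- bouts$onset
  bouts$onset <- snap(bouts$onset)
  bouts$offset <- snap(bouts$offset)
  idx <- pmin(pmax(round(stats::approx(track$time, seq_along(track$time),
                                       xout = t_p, rule = 2)$y), 1),
              length(track$time))
  behavior <- data.frame(time = t_p, x = track$x[idx], y = track$y[idx],
                         dir_deg = track$dir_deg[idx])
  list(dff = dff, bouts = bouts, behavior = behavior)
}

#' Build a peri-event (trial x time) matrix around bout onsets
#'
#' One row per bout retained; bouts whose window would run off either end
#' of the trace are dropped (and reported via the `"dropped"` attribute).
#' The time grid is inclusive at both ends, so a (-2, +4) s window at 10 Hz
#' has 61 samples.  Optional per-row scaling (min-max or z-score) is applied
#' only to the `scaled` copy used for heat maps; statistics always run on
#' the unscaled values.
#'
#' @param dff a `septodg_dff`.
#' @param bouts bout table (onset, offset, object, duration).
#' @param window c(pre, post) s relative to bout onset, pre < 0 < post.
#' @param scale `"none"`, `"minmax"`, or `"z"` for the heat-map copy.
#' @return a `septodg_perievent`: `mat` (unscaled), `scaled`, `t` (s
#'   relative to onset), `bouts` (retained), `window`.
#' @export
build_perievent <- function(dff, bouts, window = c(-2, 4), scale = "minmax") {
  stopifnot(window[1] < 0, window[2] > 0)
  fs <- 1 / stats::median(diff(dff$time))
  rel <- seq(round(window[1] * fs), round(window[2] * fs)) / fs
  keep <- logical(nrow(bouts))
  rows <- matrix(NA_real_, nrow(bouts), length(rel))
  for (i in seq_len(nrow(bouts))) {
    i0 <- which.min(abs(dff$time - bouts$onset[i]))
    idx <- i0 + round(rel * fs)
    if (idx[1] >= 1 && idx[length(idx)] <= length(dff$dff)) {
      keep[i] <- TRUE
      rows[i, ] <- dff$dff[idx]
    }
  }
  if (!any(keep)) stop("no bouts retained within the trace extent", call. = FALSE)
  mat <- rows[keep, , drop = FALSE]
  ord <- order(bouts$onset[keep])
  mat <- mat[ord, , drop = FALSE]
  kept <- bouts[keep, , drop = FALSE][ord, , drop = FALSE]
  scaled <- switch(scale,
    none = mat,
    minmax = t(apply(mat, 1, function(r) {
      rng <- range(r); if (diff(rng) == 0) r * 0 else (r - rng[1]) / diff(rng)
    })),
    z = t(apply(mat, 1, function(r) {
      s <- stats::sd(r); if (s == 0) r * 0 else (r - mean(r)) / s
    })),
    stop("unknown scale mode", call. = FALSE))
  structure(list(mat = mat, scaled = scaled, t = rel, bouts = kept,
                 window = window, dropped = sum(!keep)),
            class = "septodg_perievent")
}

#' Per-bout response scalar
#'
#' Mean dF/F during the bout (onset to onset + duration, capped at the
#' window end) minus the mean over the pre-onset window; baseline
#' subtraction can be disabled to get the raw in-bout mean.
#'
#' @param pem a `septodg_perievent`.
#' @param baseline subtract the pre-window mean (default TRUE).
#' @return numeric vector, one response per retained bout.
#' @export
bout_response <- function(pem, baseline = TRUE) {
  vapply(seq_len(nrow(pem$mat)), function(i) {
    dur <- min(pem$bouts$duration[i], pem$window[2])
    if (dur <= 0) stop("empty bout interval", call. = FALSE)
    in_bout <- pem$t >= 0 & pem$t <= dur
    pre <- pem$t < 0
    mean(pem$mat[i, in_bout]) - if (baseline) mean(pem$mat[i, pre]) else 0
  }, numeric(1))
}

#' MS-DG coupling of per-bout responses
#'
#' Pearson correlation (two-tailed, alpha 0.05) between paired per-bout DG
#' and MS response scalars.  Pairs with missing data in either site are
#' dropped; zero variance in either vector yields an explicit
#' undefined-result flag rather than a silent NaN.
#'
#' @param dg_responses,ms_responses paired numeric vectors.
#' @return a `septodg_coupling`: `r`, `p`, `n`, `df`, `undefined`, `sig`.
#' @export
coupling <- function(dg_responses, ms_responses) {
  if (length(dg_responses) != length(ms_responses))
    stop("responses must be paired (equal length)", call. = FALSE)
  ok <- is.finite(dg_responses) & is.finite(ms_responses)
  x <- dg_responses[ok]; y <- ms_responses[ok]
  if (length(x) < 3) stop("need at least 3 complete bout pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n = length(x),
                          df = length(x) - 2L, undefined = TRUE, sig = NA),
                     class = "septodg_coupling"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 df = unname(ct$parameter), undefined = FALSE,
                 sig = ct$p.value <= 0.05),
            class = "septodg_coupling")
}

#' @export
print.septodg_coupling <- function(x, ...) {
  if (x$undefined) cat("Pearson coupling: undefined (zero variance), n =",
                       x$n, "\n")
  else cat(sprintf("Pearson coupling: r = %.3f, p = %.4g, n = %d (%s)\n",
                   x$r, x$p, x$n, if (x$sig) "significant" else "n.s"))
  invisible(x)
}
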