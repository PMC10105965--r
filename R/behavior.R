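# Object-exploration bout detection and novel-place-recognition scoring.

#' Detect object-exploration bouts from head pose
#'
#' A frame counts as exploratory toward an object when the head is within
#' `proximity_cm` of the object (head point to object centre, minus
#' `object_radius_cm`) *and* the head direction is within `theta_deg` of the
#' bearing to the object.  Maximal runs of exploratory frames lasting at
#' least `min_dur_s` become bouts.  The analysis clock starts at the first
#' frame where the animal is outside every corner zone (squares of side
#' `track$corner_cm` at the arena corners); earlier frames are ignored,
#' mirroring scoring that begins once the animal leaves the corners to
#' actively explore.
#'
#' @param track a `septodg_behavior_track` (or compatible list).
#' @param theta_deg orientation cone half-angle, degrees (default 45).
#' @param min_dur_s minimum bout duration, s (default 0.25).
#' @param proximity_cm proximity criterion, cm (default 2).
#' @param object_radius_cm object radius subtracted from the centre
#'   distance (default 0).
#' @return data.frame (onset, offset, object, duration) with attribute
#'   `"clock_start"` (s).
#' @export
detect_bouts <- function(track, theta_deg = 45, min_dur_s = 0.25,
                         proximity_cm = 2, object_radius_cm = 0) {
  arena <- track$arena_cm
  for (oo in track$objects)
    if (any(oo < 0) || any(oo > arena))
      stop("object coordinates outside arena", call. = FALSE)
  fs <- track$fs %||% (1 / mean(diff(track$time)))
  cz <- track$corner_cm %||% 10
  in_corner <- (track$x <= cz | track$x >= arena - cz) &
               (track$y <= cz | track$y >= arena - cz)
  first_out <- which(!in_corner)[1]
  if (is.na(first_out)) first_out <- length(track$time) + 1L
  clock_start <- if (first_out <= length(track$time)) track$time[first_out] else Inf

  res <- list()
  for (obj in names(track$objects)) {
    oo <- track$objects[[obj]]
    d <- sqrt((track$x - oo[1])^2 + (track$y - oo[2])^2) - object_radius_cm
    bearing <- (atan2(oo[2] - track$y, oo[1] - track$x) * 180 / pi) %% 360
    expl <- d <= proximity_cm &
      angle_diff_deg(track$dir_deg, bearing) <= theta_deg &
      track$time >= clock_start
    rr <- runs_true(expl)
    if (nrow(rr)) {
      dur <- (rr$end - rr$start + 1L) / fs
      keep <- dur >= min_dur_s
      if (any(keep))
        res[[obj]] <- data.frame(onset = track$time[rr$start[keep]],
                                 offset = track$time[rr$start[keep]] + dur[keep],
                                 object = obj, duration = dur[keep],
                                 stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(onset = numeric(0), offset = numeric(0),
               object = character(0), duration = numeric(0))
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clock_start") <- clock_start
  out
}

#' Novel-place-recognition score from test-phase bouts
#'
#' `score = (t_novel - t_familiar) / (t_novel + t_familiar)`, the
#' discrimination ratio over total exploration of the relocated (novel-place)
#' and unmoved (familiar-place) objects.  Animals with zero total exploration
#' cannot be scored and are flagged excluded rather than given a value.
#'
#' @param bouts bout data.frame from [detect_bouts()] (test phase).
#' @param novel_object label of the relocated object (default `"B"`).
#' @param clock_start analysis-clock start, s; defaults to the bouts'
#'   `"clock_start"` attribute, else 0.
#' @return list of class `septodg_recognition_score`: `t_novel`,
#'   `t_familiar` (s), `score` in `[-1, 1]` (NA when excluded),
#'   `latency_to_first_bout` (s), `excluded` flag.
#' @export
recognition_score <- function(bouts, novel_object = "B", clock_start = NULL) {
  clock_start <- clock_start %||% attr(bouts, "clock_start") %||% 0
  t_by <- tapply(bouts$duration, bouts$object, sum)
  objs <- unique(bouts$object)
  t_nov <- unname(t_by[novel_object]); t_nov <- if (is.na(t_nov)) 0 else t_nov
  t_fam <- sum(bouts$duration) - t_nov
  total <- t_nov + t_fam
  excluded <- total <= 0
  structure(list(
    t_novel = t_nov, t_familiar = t_fam,
    score = if (excluded) NA_real_ else (t_nov - t_fam) / total,
    latency_to_first_bout = if (nrow(bouts)) min(bouts$onset) - clock_start
                            else NA_real_,
    excluded = excluded
  ), class = "septodg_recognition_score")
}

#' Group comparison of recognition behavior
#'
#' Unpaired two-tailed t-tests on recognition score and latency across
#' genotypes, plus a paired t-test on within-animal object A vs B
#' exploration times.  Degenerate inputs (zero variance) yield an NA
#' statistic with a note instead of an error.
#'
#' @param scores data.frame with columns `animal`, `genotype`, `score`,
#'   `latency`, `t_A`, `t_B` (per-animal test-phase summaries; `t_A`/`t_B`
#'   optional for the paired contrast).
#' @return data.frame of comparison rows (measure, test, statistic, df, p,
#'   n per group, means, sig).
#' @export
group_behavior_compare <- function(scores) {
  gr <- unique(scores$genotype)
  if (length(gr) != 2) stop("exactly two genotype groups required", call. = FALSE)
  if (any(table(scores$genotype) < 2))
    stop("each group needs at least 2 animals", call. = FALSE)
  rows <- list()
  for (m in intersect(c("score", "latency"), names(scores))) {
    rows[[m]] <- run_comparison(
      data.frame(value = scores[[m]], group = scores$genotype),
      comparison_spec("unpaired_t", unit = "animal", measure = m))
  }
  if (all(c("t_A", "t_B") %in% names(scores))) {
    rows[["object_time"]] <- run_comparison(
      data.frame(x = scores$t_A, y = scores$t_B),
      comparison_spec("paired_t", unit = "animal", measure = "t_A_vs_t_B"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
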