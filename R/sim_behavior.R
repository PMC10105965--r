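# Synthetic behavior tracks for the novel-place-recognition arena.

#' Simulate a 20 Hz behavior track with scripted exploration bouts
#'
#' Head position and direction in a 45 x 45 cm arena.  The trajectory is a
#' bounded random walk, except that a *scripted* list of exploration bouts
#' (known onsets, durations and target object) drives the pose during bouts:
#' the head is placed within 2 cm of the target object and oriented straight
#' at it, so a correct bout detector recovers the script exactly (to video
#' frame quantisation).  The animal starts in an arena corner and leaves it
#' after `corner_dwell_s`; the scripted analysis clock therefore starts when
#' the corner is left, mirroring how scoring is anchored in the assay.
#' In the test phase object B is relocated to a novel position.
#'
#' @param cfg a [sim_config()].
#' @param phase `"familiarization"` or `"test"`.
#' @param n_bouts,bout_dur_s override the config script size.
#' @param objects optional named list `A`, `B` of (x, y) cm.
#' @param object_probs probabilities of a scripted bout targeting A vs B
#'   (default balanced); biasing toward the relocated object models intact
#'   place recognition in the test phase.
#' @param corner_dwell_s time spent in the start corner, s (default 5).
#' @param seed optional; defaults to a [child_seed()].
#' @return a `septodg_behavior_track`: list with `time`, `x`, `y`,
#'   `dir_deg`, `objects`, `arena_cm`, `corner_cm`, `phase`, `fs`, and the
#'   ground-truth `bouts` data.frame (onset, offset, object, duration).
#' @export
simulate_behavior_track <- function(cfg, phase = "familiarization",
                                    n_bouts = NULL, bout_dur_s = NULL,
                                    objects = NULL, corner_dwell_s = 5,
                                    object_probs = c(A = 0.5, B = 0.5),
                                    seed = NULL) {
  if (!phase %in% c("familiarization", "test"))
    stop("phase must be 'familiarization' or 'test'", call. = FALSE)
  b <- cfg$behavior
  n_bouts <- n_bouts %||% b$n_bouts
  bout_dur_s <- bout_dur_s %||% b$bout_dur_s
  seed <- seed %||% child_seed(cfg$seed, paste("behavior", phase, sep = "/"))
  set.seed(seed)

  fs <- cfg$photometry$fs_video
  arena <- b$arena_cm
  time <- seq(0, b$duration_s, by = 1 / fs)
  n <- length(time)
  if (is.null(objects)) {
    objects <- list(A = c(12, 12), B = c(33, 12))
    if (phase == "test") objects$B <- c(33, 33)  # relocated (novel place)
  }

  # schedule non-overlapping bouts on the video frame grid, after corner
  # exit; the 4 s guard keeps one bout's calcium decay out of the next
  # bout's pre-onset baseline window in peri-event analyses
  clock0 <- corner_dwell_s + 2
  gap <- 4
  slot <- bout_dur_s + gap
  avail <- b$duration_s - clock0 - bout_dur_s - 1
  if (n_bouts * slot > avail)
    stop("too many bouts for the track duration", call. = FALSE)
  starts <- clock0 + sort(sample.int(floor(avail / slot), n_bouts)) * slot +
    stats::runif(n_bouts, 0, gap / 2)
  onsets <- round(starts * fs) / fs
  offsets <- round((starts + bout_dur_s) * fs) / fs
  obj_lab <- if (abs(object_probs[["A"]] - object_probs[["B"]]) < 1e-12)
    sample(rep(c("A", "B"), length.out = n_bouts))
  else sample(c("A", "B"), n_bouts, replace = TRUE,
              prob = object_probs[c("A", "B")])
  bouts <- data.frame(onset = onsets, offset = offsets, object = obj_lab,
                      duration = offsets - onsets,
                      stringsAsFactors = FALSE)

  # bounded random walk, corner start, repelled from objects outside bouts
  x <- numeric(n); y <- numeric(n); dir <- numeric(n)
  x[1] <- 3; y[1] <- 3; dir[1] <- 45
  step <- b$speed_cm_s / fs
  dwell_n <- round(corner_dwell_s * fs)
  for (i in 2:n) {
    if (i <= dwell_n) {               # sit in the start corner
      x[i] <- 3 + stats::rnorm(1, 0, 0.2); y[i] <- 3 + stats::rnorm(1, 0, 0.2)
      x[i] <- min(max(x[i], 1), b$corner_cm - 1)
      y[i] <- min(max(y[i], 1), b$corner_cm - 1)
      dir[i] <- (dir[i - 1] + stats::rnorm(1, 0, 10)) %% 360
      next
    }
    dir[i] <- (dir[i - 1] + stats::rnorm(1, 0, 20)) %% 360
    x[i] <- x[i - 1] + step * cospi(dir[i] / 180)
    y[i] <- y[i - 1] + step * sinpi(dir[i] / 180)
    # reflect at walls
    if (x[i] < 1 || x[i] > arena - 1) {
      x[i] <- min(max(x[i], 1), arena - 1); dir[i] <- (180 - dir[i]) %% 360
    }
    if (y[i] < 1 || y[i] > arena - 1) {
      y[i] <- min(max(y[i], 1), arena - 1); dir[i] <- (-dir[i]) %% 360
    }
    # keep accidental approaches out of the 2 cm exploration zone
    for (oo in objects) {
      d <- sqrt((x[i] - oo[1])^2 + (y[i] - oo[2])^2)
      if (d < 3.5) {
        push <- (3.5 - d) + 0.1
        x[i] <- x[i] + push * (x[i] - oo[1]) / max(d, 0.1)
        y[i] <- y[i] + push * (y[i] - oo[2]) / max(d, 0.1)
      }
    }
  }

  # overwrite scripted bout frames: head within 2 cm, oriented at object
  for (k in seq_len(n_bouts)) {
    idx <- which(time >= bouts$onset[k] & time < bouts$offset[k])
    oo <- objects[[bouts$object[k]]]
    ang <- stats::runif(1, 0, 360)
    r <- stats::runif(1, 0.5, 1.5)
    x[idx] <- oo[1] + r * cospi(ang / 180) + stats::rnorm(length(idx), 0, 0.05)
    y[idx] <- oo[2] + r * sinpi(ang / 180) + stats::rnorm(length(idx), 0, 0.05)
    dir[idx] <- (atan2(oo[2] - y[idx], oo[1] - x[idx]) * 180 / pi) %% 360
  }

  structure(list(
    time = time, x = x, y = y, dir_deg = dir %% 360,
    objects = objects, arena_cm = arena, corner_cm = b$corner_cm,
    phase = phase, fs = fs, bouts = bouts, seed = seed
  ), class = "septodg_behavior_track")
}
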