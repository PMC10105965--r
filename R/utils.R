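# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a global seed and a stage tag
#'
#' All generators draw their randomness from child seeds derived
#' deterministically from one global seed, so stages can be re-run in
#' isolation without cross-contaminating each other's streams.
#'
#' @param seed integer global seed.
#' @param tag character stage label (e.g. `"photometry/WT/animal3/DG"`).
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps results in 32-bit range
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end) (indices)
runs_true <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0)
  if (!ok) stop(sprintf("`%s` must be a single %s number", name,
                        if (allow_zero) "non-negative" else "positive"),
                call. = FALSE)
  invisible(x)
}

# angular difference in degrees, folded to [0, 180]
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# robust noise SD via median absolute deviation
mad_sd <- function(x) stats::mad(x, constant = 1.4826)
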