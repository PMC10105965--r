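# Shared fixtures and independent oracles for the test suite.

# small, fast simulation config
quick_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, ...)
}

# independent flood-fill component labeling (stack-based, same
# connectivity as label_components) -- the oracle for the graph labeler
floodfill_labels <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lab <- array(0L, dims)
  nextlab <- 0L
  fg <- which(mask)
  for (s in fg) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    stack <- s
    lab[s] <- nextlab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        lin <- nb[1] + if (nd >= 2) (nb[2] - 1) * dims[1] else 0
        if (nd == 3) lin <- lin + (nb[3] - 1) * dims[1] * dims[2]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nextlab
          stack <- c(stack, lin)
        }
      }
    }
  }
  attr(lab, "n") <- nextlab
  lab
}

# do two labelings define the same partition of foreground voxels?
same_partition <- function(a, b) {
  fg <- which(a > 0)
  if (!identical(fg, which(b > 0))) return(FALSE)
  identical(as.integer(factor(a[fg], levels = unique(a[fg]))),
            as.integer(factor(b[fg], levels = unique(b[fg]))))
}

# F1 score matching detected event onsets to true times within `tol` s
event_f1 <- function(detected, truth, tol = 0.3) {
  if (!length(detected) && !length(truth)) return(1)
  if (!length(detected) || !length(truth)) return(0)
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  prec <- tp / length(detected)
  rec <- tp / length(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# hand-built behavior track: constant pose segments on a 20 Hz grid
manual_track <- function(segments, objects = list(A = c(12, 12),
                                                  B = c(33, 12)),
                         fs = 20, arena = 45, corner_cm = 10) {
  time <- x <- y <- dir <- numeric(0)
  t0 <- 0
  for (sg in segments) {
    n <- round(sg$dur * fs)
    time <- c(time, t0 + seq_len(n) / fs - 1 / fs)
    x <- c(x, rep(sg$x, n)); y <- c(y, rep(sg$y, n))
    dir <- c(dir, rep(sg$dir, n))
    t0 <- t0 + n / fs
  }
  structure(list(time = time, x = x, y = y, dir_deg = dir %% 360,
                 objects = objects, arena_cm = arena, corner_cm = corner_cm,
                 phase = "test", fs = fs,
                 bouts = data.frame(onset = numeric(0), offset = numeric(0),
                                    object = character(0),
                                    duration = numeric(0))),
            class = "septodg_behavior_track")
}
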