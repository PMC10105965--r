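# Synthetic tracing images: retrograde section sets and anterograde volumes.
#
# Conventions (used everywhere): arrays are (z, y, x) for volumes and
# (y, x) for sections; voxel/pixel centres sit at (i - 0.5) * voxel size;
# masks specified by bounds are half-open boxes.

# physical centre coordinates of all voxels inside an index bounding box
voxel_centers <- function(idx_lo, idx_hi, voxel_um) {
  ax <- lapply(seq_along(idx_lo), function(d)
    (seq(idx_lo[d], idx_hi[d]) - 0.5) * voxel_um[d])
  g <- as.matrix(expand.grid(ax, KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- NULL
  g
}

# voxels (linear indices) whose centre lies within `radius` of segment p0-p1
rasterize_capsule <- function(dims, voxel_um, p0, p1, radius) {
  lo <- pmax(1L, floor(pmin(p0, p1) - radius) / voxel_um)
  hi <- pmin(dims, ceiling((pmax(p0, p1) + radius) / voxel_um) + 1L)
  lo <- pmax(1L, as.integer(floor(lo)))
  hi <- as.integer(pmin(dims, hi))
  if (any(hi < lo)) return(integer(0))
  ctr <- voxel_centers(lo, hi, voxel_um)
  v <- p1 - p0
  L2 <- sum(v^2)
  w <- sweep(ctr, 2, p0)
  tpar <- if (L2 > 0) pmin(pmax(as.numeric(w %*% v) / L2, 0), 1) else 0
  closest <- outer(tpar, v) + matrix(p0, nrow(ctr), 3, byrow = TRUE)
  d2 <- rowSums((ctr - closest)^2)
  inside <- d2 <= radius^2
  if (!any(inside)) return(integer(0))
  co <- as.matrix(expand.grid(lapply(seq_along(lo), function(d)
    seq(lo[d], hi[d]))))[inside, , drop = FALSE]
  as.integer(co[, 1] + (co[, 2] - 1) * dims[1] +
               (co[, 3] - 1) * dims[1] * dims[2])
}

# pixels of a disk in a (y, x) image, physical centre/radius in um
rasterize_disk <- function(dims, pixel_um, center, radius) {
  lo <- pmax(1L, as.integer(floor((center - radius) / pixel_um)))
  hi <- pmin(dims, as.integer(ceiling((center + radius) / pixel_um)) + 1L)
  if (any(hi < lo)) return(integer(0))
  yy <- (seq(lo[1], hi[1]) - 0.5) * pixel_um[1]
  xx <- (seq(lo[2], hi[2]) - 0.5) * pixel_um[2]
  g <- expand.grid(y = seq(lo[1], hi[1]), x = seq(lo[2], hi[2]))
  gy <- (g$y - 0.5) * pixel_um[1]; gx <- (g$x - 0.5) * pixel_um[2]
  inside <- (gy - center[1])^2 + (gx - center[2])^2 <= radius^2
  as.integer(g$y[inside] + (g$x[inside] - 1) * dims[1])
}

# box mask helper; bounds are half-open index boxes [lo, hi)
box_mask <- function(dims, lo, hi) {
  m <- array(FALSE, dims)
  idx <- lapply(seq_along(dims), function(d) seq(lo[d], hi[d] - 1L))
  do.call(`[<-`, c(list(m), idx, list(TRUE)))
}

# default retrograde region layout: named boxes tiled on one section image
default_region_layout <- function(dims) {
  regions <- c("MS", "DB", "VTA", "cCA", "cDG", "HY", "ENT", "DR",
               "LS", "TH", "SUB", "PIR", "mPFC", "LC")
  ncol_ <- 4L
  bw <- floor(dims[2] / ncol_); bh <- floor(dims[1] / 4L)
  out <- list()
  for (i in seq_along(regions)) {
    r <- (i - 1L) %/% ncol_; c_ <- (i - 1L) %% ncol_
    lo <- c(r * bh + 6L, c_ * bw + 6L)
    hi <- c((r + 1L) * bh - 5L, (c_ + 1L) * bw - 5L)
    out[[regions[i]]] <- box_mask(dims, lo + 1L, hi + 1L)
  }
  out
}

#' Simulate tracing imagery with known ground truth
#'
#' Two modes mirroring the two tracing experiments:
#'
#' * `"retrograde_sections"`: a set of 2D coronal-section images (pixel
#'   size `pixel_um`, section thickness 40 um, every 6th section sampled)
#'   with mCherry-positive somata distributed across named anatomical ROI
#'   boxes (MS, DB, VTA, ...) at configured relative densities, a starter
#'   (DG) region with a painted mCherry starter area, and a GABA channel in
#'   which a `coloc_frac` Bernoulli subset of the MS somata is co-labeled.
#'
#' * `"anterograde_volume"`: a 3D volume with randomly oriented
#'   capsule-shaped YFP processes inside a hilus ROI, plus a companion 2D
#'   MS image with non-touching YFP somata for the starter-cell-density
#'   denominator.
#'
#' Ground truth records true painted areas/volumes (as voxelized unions),
#' counts, and the realized co-labeled fraction.
#'
#' @param cfg a [sim_config()].
#' @param mode `"retrograde_sections"` or `"anterograde_volume"`.
#' @param n_sections number of sampled sections (retrograde; default 3).
#' @param region_weights named relative soma densities (retrograde).
#' @param seed optional.
#' @return `list(data, rois, truth)`; see Details in the fields of each.
#' @export
simulate_tracing_volume <- function(cfg,
                                    mode = c("anterograde_volume",
                                             "retrograde_sections"),
                                    n_sections = 3L,
                                    region_weights = NULL, seed = NULL) {
  mode <- match.arg(mode)
  im <- cfg$imaging
  seed <- seed %||% child_seed(cfg$seed, paste("tracing", mode, sep = "/"))
  set.seed(seed)
  if (mode == "anterograde_volume") {
    simulate_anterograde(im, seed)
  } else {
    simulate_retrograde(im, n_sections, region_weights, seed)
  }
}

simulate_anterograde <- function(im, seed) {
  dims <- as.integer(im$shape)            # (z, y, x)
  vx <- rep(im$voxel_um, length.out = 3)
  phys <- dims * vx
  vol <- array(0, dims)

  # hilus ROI: central box over the full z extent (extruded section volume)
  my <- max(2L, round(dims[2] * 0.1)); mx <- max(2L, round(dims[3] * 0.1))
  roi <- box_mask(dims, c(1L, my + 1L, mx + 1L),
                  c(dims[1] + 1L, dims[2] - my + 1L, dims[3] - mx + 1L))
  if (length(roi) != length(vol)) stop("ROI mask does not fit the volume")

  union_idx <- integer(0)
  n <- im$n_processes
  if (n > 0) {
    for (i in seq_len(n)) {
      ctr <- c(stats::runif(1, 0.15, 0.85) * phys[1],
               stats::runif(1, 0.2, 0.8) * phys[2],
               stats::runif(1, 0.2, 0.8) * phys[3])
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      half <- im$tube_len_um / 2
      idx <- rasterize_capsule(dims, vx, ctr - half * u, ctr + half * u,
                               im$tube_radius_um)
      union_idx <- c(union_idx, idx)
    }
    union_idx <- unique(union_idx)
    vol[union_idx] <- im$signal
  }
  vol <- vol + im$background +
    array(stats::rnorm(length(vol), 0, im$noise_sd), dims)

  # companion MS image with non-touching somata (density denominator)
  ms_dims <- c(200L, 200L)
  ms_px <- c(1, 1)
  ms_img <- matrix(0, ms_dims[1], ms_dims[2])
  n_soma <- max(0L, round(im$n_somata / 4))
  centers <- place_nonoverlapping(n_soma, ms_dims * ms_px,
                                  2 * im$soma_radius_um + 2)
  for (i in seq_len(nrow(centers)))
    ms_img[rasterize_disk(ms_dims, ms_px, centers[i, ], im$soma_radius_um)] <-
      im$signal
  ms_img <- ms_img + im$background +
    matrix(stats::rnorm(length(ms_img), 0, im$noise_sd), ms_dims[1])
  ms_roi <- matrix(TRUE, ms_dims[1], ms_dims[2])

  attr(vol, "voxel_um") <- vx
  attr(ms_img, "pixel_um") <- ms_px
  list(
    data = list(volume = vol, ms_image = ms_img),
    rois = list(hilus = roi, ms = ms_roi),
    truth = list(n_processes = n,
                 true_volume_um3 = length(union_idx) * prod(vx),
                 n_somata_ms = n_soma,
                 ms_area_um2 = prod(ms_dims * ms_px),
                 soma_density = n_soma / (prod(ms_dims * ms_px) * 40),
                 seed = seed))
}

# rejection-sample n centres with pairwise spacing >= min_sep (um)
place_nonoverlapping <- function(n, extent_um, min_sep, margin = NULL) {
  margin <- margin %||% (min_sep / 2 + 1)
  out <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(out) < n && tries < 200 * max(n, 1)) {
    p <- c(stats::runif(1, margin, extent_um[1] - margin),
           stats::runif(1, margin, extent_um[2] - margin))
    if (!nrow(out) || min(sqrt(rowSums(sweep(out, 2, p)^2))) >= min_sep)
      out <- rbind(out, p)
    tries <- tries + 1
  }
  if (nrow(out) < n)
    warning("could not place all somata without overlap; placed ", nrow(out))
  out
}

simulate_retrograde <- function(im, n_sections, region_weights, seed) {
  if (is.null(region_weights))
    region_weights <- c(MS = 1, DB = 0.7, VTA = 0.25, cCA = 0.2, cDG = 0.18,
                        HY = 0.15, ENT = 0.12, DR = 0.1, LS = 0.1, TH = 0.08,
                        SUB = 0.06, PIR = 0.05, mPFC = 0.04, LC = 0.03)
  dims <- c(360L, 360L)
  px <- c(2, 2)                            # um per pixel
  rois <- default_region_layout(dims)
  rois <- rois[names(rois) %in% names(region_weights)]

  # exact MS count (split across sections), Poisson counts elsewhere
  ms_total <- im$n_somata
  ms_per_sec <- diff(round(seq(0, ms_total, length.out = n_sections + 1)))
  sections <- vector("list", n_sections)
  counts <- stats::setNames(numeric(length(rois)), names(rois))
  ms_centers_all <- list()
  coloc_idx_all <- list()
  r_soma <- im$soma_radius_um
  for (s in seq_len(n_sections)) {
    mch <- matrix(0, dims[1], dims[2])
    gaba <- matrix(0, dims[1], dims[2])
    for (rg in names(rois)) {
      n_rg <- if (rg == "MS") ms_per_sec[s] else
        stats::rpois(1, region_weights[[rg]] / region_weights[["MS"]] *
                       ms_total / n_sections)
      bb <- which(rois[[rg]], arr.ind = TRUE)
      lo <- apply(bb, 2, min); hi <- apply(bb, 2, max)
      ext_lo <- (lo - 1) * px; ext_hi <- hi * px
      ctr <- matrix(numeric(0), 0, 2)
      tries <- 0
      while (nrow(ctr) < n_rg && tries < 400 * max(n_rg, 1)) {
        p <- c(stats::runif(1, ext_lo[1] + r_soma + 1, ext_hi[1] - r_soma - 1),
               stats::runif(1, ext_lo[2] + r_soma + 1, ext_hi[2] - r_soma - 1))
        if (!nrow(ctr) ||
            min(sqrt(rowSums(sweep(ctr, 2, p)^2))) >= 2 * r_soma + 2)
          ctr <- rbind(ctr, p)
        tries <- tries + 1
      }
      for (i in seq_len(nrow(ctr)))
        mch[rasterize_disk(dims, px, ctr[i, ], r_soma)] <- im$signal
      counts[rg] <- counts[rg] + nrow(ctr)
      if (rg == "MS" && nrow(ctr)) {
        co <- stats::runif(nrow(ctr)) < im$coloc_frac
        for (i in which(co))
          gaba[rasterize_disk(dims, px, ctr[i, ], r_soma)] <- im$signal
        ms_centers_all[[s]] <- ctr
        coloc_idx_all[[s]] <- co
      }
    }
    mch <- mch + im$background +
      matrix(stats::rnorm(length(mch), 0, im$noise_sd), dims[1])
    gaba <- gaba + im$background +
      matrix(stats::rnorm(length(gaba), 0, im$noise_sd), dims[1])
    attr(mch, "pixel_um") <- px; attr(gaba, "pixel_um") <- px
    sections[[s]] <- list(mcherry = mch, gaba = gaba)
  }

  # starter (DG) section: painted mCherry blob inside a starter ROI
  starter_img <- matrix(0, dims[1], dims[2])
  starter_roi <- box_mask(dims, c(121L, 121L), c(241L, 241L))
  blob_idx <- integer(0)
  for (i in seq_len(25)) {
    ctr <- c(stats::runif(1, 280, 440), stats::runif(1, 280, 440))
    blob_idx <- c(blob_idx, rasterize_disk(dims, px, ctr,
                                           stats::runif(1, 8, 16)))
  }
  blob_idx <- unique(blob_idx)
  starter_img[blob_idx] <- im$signal
  starter_img <- starter_img + im$background +
    matrix(stats::rnorm(length(starter_img), 0, im$noise_sd), dims[1])
  attr(starter_img, "pixel_um") <- px

  true_region_area <- counts * pi * r_soma^2   # analytic; voxelized below
  list(
    data = list(sections = sections, starter_image = starter_img),
    rois = c(rois, list(starter_DG = starter_roi)),
    truth = list(counts = counts,
                 region_weights = region_weights,
                 region_area_um2 = true_region_area,
                 starter_area_um2 = length(blob_idx) * prod(px),
                 ms_soma_count = sum(vapply(ms_centers_all, nrow, numeric(1))),
                 coloc_count = sum(unlist(coloc_idx_all)),
                 coloc_frac_realized =
                   sum(unlist(coloc_idx_all)) /
                   max(1, sum(vapply(ms_centers_all, nrow, numeric(1)))),
                 seed = seed),
    pixel_um = px
  )
}
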