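# Quantification of tracing imagery: thresholding, connected components,
# soma counting, co-localization, connectivity ratio, projection density.

#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance on a 256-bin histogram; the returned
#' cut classifies a value as positive when strictly greater.
#'
#' @param x numeric vector (or array) of intensities.
#' @param n_bins histogram resolution (default 256).
#' @return scalar threshold; `Inf` for a constant input.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(Inf)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Threshold an image channel into a binary mask
#'
#' @param img numeric matrix (section) or 3D array (volume).
#' @param method `"otsu"` (default), `"fixed"`, or `"percentile"`.
#' @param value fixed threshold, or percentile in `[0, 1]`.
#' @return logical mask with attribute `"threshold"` (the value used,
#'   logged for reproducibility).  A constant channel yields an empty mask
#'   with a warning.
#' @export
threshold_channel <- function(img, method = c("otsu", "fixed", "percentile"),
                              value = NULL) {
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsu_threshold(img),
    fixed = { stopifnot(is.numeric(value)); value },
    percentile = {
      stopifnot(is.numeric(value), value >= 0, value <= 1)
      stats::quantile(img, value, names = FALSE)
    })
  if (!is.finite(thr)) {
    warning("constant-intensity channel: empty mask")
    thr <- Inf
  }
  m <- img > thr
  attr(m, "threshold") <- thr
  m
}

#' Label connected components of a binary mask
#'
#' 26-connectivity for 3D volumes, 8-connectivity for 2D sections (the
#' maximal standard neighborhoods).  Foreground voxels are joined into an
#' adjacency graph and labelled by graph components.
#'
#' @param mask logical matrix or 3D array.
#' @return integer array of the same shape (0 = background, 1..n labels)
#'   with attribute `"n"` (component count).
#' @export
label_components <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  stopifnot(nd %in% c(2L, 3L))
  lab <- array(0L, dims)
  fg <- which(mask)
  if (!length(fg)) { attr(lab, "n") <- 0L; return(lab) }
  idmap <- array(0L, dims)
  idmap[fg] <- seq_along(fg)
  co <- arrayInd(fg, dims)
  # half set of neighbor offsets (the rest follow by symmetry)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  first_nz <- apply(offs, 1, function(o) o[which(o != 0)[1]])
  offs <- offs[first_nz > 0, , drop = FALSE]
  strides <- cumprod(c(1, dims[-nd]))
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- rep(TRUE, nrow(co))
    for (d in seq_len(nd)) {
      nc <- co[, d] + o[d]
      ok <- ok & nc >= 1L & nc <= dims[d]
    }
    if (!any(ok)) next
    nb_lin <- fg[ok] + as.integer(sum(o * strides))
    nb_id <- idmap[nb_lin]
    hit <- nb_id > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb_id[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # renumber so labels are dense 1..n in first-voxel order
  memb <- as.integer(factor(memb, levels = unique(memb)))
  lab[fg] <- memb
  attr(lab, "n") <- max(memb)
  lab
}

# brute-force Euclidean distance transform of a small 2D mask (um units)
distance_transform2d <- function(mask, pixel_um = c(1, 1)) {
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  d <- numeric(nrow(fg))
  if (!nrow(bg)) { d[] <- Inf }
  else {
    bgy <- bg[, 1] * pixel_um[1]; bgx <- bg[, 2] * pixel_um[2]
    for (i in seq_len(nrow(fg))) {
      d[i] <- sqrt(min((fg[i, 1] * pixel_um[1] - bgy)^2 +
                         (fg[i, 2] * pixel_um[2] - bgx)^2))
    }
  }
  out <- matrix(0, nrow(mask), ncol(mask))
  out[mask] <- d
  out
}

# split one 2D component into somata via distance-transform peaks:
# peaks are local maxima of the EDT separated by >= min_diam; pixels are
# assigned to the nearest peak (a compact stand-in for marker-based
# watershed that resolves touching somata).
split_component2d <- function(mask, pixel_um, min_diam_um) {
  dt <- distance_transform2d(mask, pixel_um)
  fg <- which(mask, arr.ind = TRUE)
  vals <- dt[mask]
  o <- order(vals, decreasing = TRUE)
  peaks <- matrix(numeric(0), 0, 2)
  for (i in o) {
    if (vals[i] < min_diam_um / 4) break
    p <- fg[i, ] * pixel_um
    if (!nrow(peaks) ||
        min(sqrt(rowSums(sweep(peaks, 2, p)^2))) >= min_diam_um)
      peaks <- rbind(peaks, p)
  }
  if (nrow(peaks) < 2) return(list(n = 1L, assign = rep(1L, nrow(fg))))
  py <- fg[, 1] * pixel_um[1]; px_ <- fg[, 2] * pixel_um[2]
  d2 <- outer(py, peaks[, 1], `-`)^2 + outer(px_, peaks[, 2], `-`)^2
  list(n = nrow(peaks), assign = max.col(-d2))
}

#' Count labeled cells within an ROI
#'
#' Blob detection: threshold (Otsu by default), connected components within
#' the ROI, and distance-transform splitting of merged blobs larger than a
#' single soma (2D sections only; two somata touching at one pixel count
#' as two).  Density follows the cells / (ROI area x 40 um) convention of
#' 40-um-thick sections.
#'
#' @param img intensity matrix (2D) or array (3D).
#' @param roi logical mask congruent with `img`.
#' @param pixel_um physical pixel size (per axis); defaults to the image's
#'   `"pixel_um"`/`"voxel_um"` attribute or 1.
#' @param min_diameter_um minimum soma diameter (default 8).
#' @param section_um section thickness for the density denominator (40).
#' @param method,value threshold configuration, see [threshold_channel()].
#' @return list `count`, `density` (cells/um^3), `roi_area_um2`,
#'   `threshold`.
#' @export
count_cells <- function(img, roi = NULL, pixel_um = NULL,
                        min_diameter_um = 8, section_um = 40,
                        method = "otsu", value = NULL) {
  pixel_um <- pixel_um %||% attr(img, "pixel_um") %||%
    attr(img, "voxel_um") %||% rep(1, length(dim(img)))
  if (is.null(roi)) roi <- array(TRUE, dim(img))
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  m <- suppressWarnings(threshold_channel(img, method, value))
  m <- m & roi
  lab <- label_components(m)
  n <- attr(lab, "n")
  count <- 0L
  if (n > 0) {
    if (length(dim(img)) == 2) {
      exp_area <- pi * (min_diameter_um / 2)^2
      px_area <- prod(pixel_um)
      for (k in seq_len(n)) {
        comp <- lab == k
        area <- sum(comp) * px_area
        if (area < exp_area * 0.2) next          # debris
        if (area > exp_area * 1.8) {
          count <- count + split_component2d(comp, pixel_um,
                                             min_diameter_um)$n
        } else count <- count + 1L
      }
    } else count <- n
  }
  area <- sum(roi) * prod(pixel_um)
  list(count = count, density = count / (area * section_um),
       roi_area_um2 = area, threshold = attr(m, "threshold"))
}

#' Fraction of mCherry-positive somata co-labeled in a GABA channel
#'
#' Somata are detected as blobs in the mCherry channel; a soma is GABA
#' positive when the mean GABA intensity over its footprint exceeds the
#' GABA channel's Otsu threshold.  With no detectable mCherry somata the
#' fraction is undefined.
#'
#' @param mcherry,gaba intensity matrices (one section) or lists of
#'   matrices (section sets, pooled).
#' @param roi optional mask restricting the count (e.g. the MS box).
#' @param pixel_um physical pixel size.
#' @param min_diameter_um minimum soma diameter (default 8).
#' @return list `fraction`, `n_total`, `n_coloc`, `undefined`.
#' @export
colocalization_fraction <- function(mcherry, gaba, roi = NULL,
                                    pixel_um = NULL, min_diameter_um = 8) {
  if (is.list(mcherry)) {
    parts <- lapply(seq_along(mcherry), function(i)
      colocalization_fraction(mcherry[[i]], gaba[[i]], roi, pixel_um,
                              min_diameter_um))
    n_tot <- sum(vapply(parts, `[[`, numeric(1), "n_total"))
    n_col <- sum(vapply(parts, `[[`, numeric(1), "n_coloc"))
    return(list(fraction = if (n_tot > 0) n_col / n_tot else NA_real_,
                n_total = n_tot, n_coloc = n_col, undefined = n_tot == 0))
  }
  pixel_um <- pixel_um %||% attr(mcherry, "pixel_um") %||% c(1, 1)
  m <- suppressWarnings(threshold_channel(mcherry, "otsu"))
  if (!is.null(roi)) m <- m & roi
  lab <- label_components(m)
  n <- attr(lab, "n")
  if (n == 0) return(list(fraction = NA_real_, n_total = 0L, n_coloc = 0L,
                          undefined = TRUE))
  g_thr <- otsu_threshold(gaba)
  exp_area <- pi * (min_diameter_um / 2)^2
  px_area <- prod(pixel_um)
  n_total <- 0L; n_coloc <- 0L
  for (k in seq_len(n)) {
    comp <- lab == k
    area <- sum(comp) * px_area
    if (area < exp_area * 0.2) next
    if (area > exp_area * 1.8) {
      sp <- split_component2d(comp, pixel_um, min_diameter_um)
      fgi <- which(comp)
      for (s in seq_len(sp$n)) {
        foot <- fgi[sp$assign == s]
        n_total <- n_total + 1L
        if (is.finite(g_thr) && mean(gaba[foot]) > g_thr)
          n_coloc <- n_coloc + 1L
      }
    } else {
      n_total <- n_total + 1L
      if (is.finite(g_thr) && mean(gaba[comp]) > g_thr)
        n_coloc <- n_coloc + 1L
    }
  }
  if (n_total == 0) return(list(fraction = NA_real_, n_total = 0L,
                                n_coloc = 0L, undefined = TRUE))
  list(fraction = n_coloc / n_total, n_total = n_total, n_coloc = n_coloc,
       undefined = FALSE)
}

#' Connectivity ratio of presynaptic input regions
#'
#' For each input region: thresholded mCherry area within the region,
#' summed over the sampled sections, divided by the thresholded mCherry
#' starter area in the DG.  One threshold (global Otsu over all section
#' images) is used per batch so genotypes are treated identically.
#'
#' @param sections list of mCherry intensity matrices (one per section).
#' @param rois named list of region masks (applied to every section).
#' @param starter_img starter-section mCherry intensity matrix.
#' @param starter_roi mask of the starter (DG) region.
#' @param pixel_um physical pixel size.
#' @param method,value threshold configuration.
#' @return a `septodg_connectivity`: data.frame ranking (region,
#'   area_um2, ratio) plus `starter_area_um2`, `threshold`, `undefined`.
#' @export
connectivity_ratio <- function(sections, rois, starter_img, starter_roi,
                               pixel_um = NULL, method = "otsu",
                               value = NULL) {
  pixel_um <- pixel_um %||% attr(sections[[1]], "pixel_um") %||% c(1, 1)
  px_area <- prod(pixel_um)
  pooled <- c(unlist(lapply(sections, as.numeric)), as.numeric(starter_img))
  thr <- switch(method,
    otsu = otsu_threshold(pooled),
    fixed = value,
    percentile = stats::quantile(pooled, value, names = FALSE))
  starter_area <- sum(starter_img > thr & starter_roi) * px_area
  areas <- vapply(names(rois), function(rg)
    sum(vapply(sections, function(s) sum(s > thr & rois[[rg]]), numeric(1))),
    numeric(1)) * px_area
  undefined <- starter_area <= 0
  tab <- data.frame(region = names(rois), area_um2 = unname(areas),
                    ratio = if (undefined) NA_real_ else
                      unname(areas) / starter_area,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$area_um2), ]
  rownames(tab) <- NULL
  structure(list(ranking = tab, starter_area_um2 = starter_area,
                 threshold = thr, undefined = undefined),
            class = "septodg_connectivity")
}

#' 3D reconstruction of labeled processes and projection density
#'
#' Replaces a commercial surface reconstruction with a transparent
#' procedure preserving the same observables: threshold the YFP channel
#' (one logged threshold per batch), label 26-connected components inside
#' the extruded hilus ROI, sum per-object voxel volumes, and normalise by
#' hilus ROI volume and (when available) the MS starter-cell density.
#'
#' @param volume 3D intensity array (z, y, x).
#' @param hilus_roi logical mask congruent with `volume`.
#' @param voxel_um voxel size per axis, um.
#' @param cell_density MS starter-cell density (cells/um^3) for the final
#'   normalisation; `NULL` flags the result unnormalised.
#' @param method,value threshold configuration.
#' @return a `septodg_projection`: `n_objects`, `object_volumes_um3`,
#'   `summed_volume_um3`, `roi_volume_um3`, `density` (volume fraction),
#'   `normalized_density`, `threshold`, `normalized` flag.
#' @export
reconstruct_processes_3d <- function(volume, hilus_roi, voxel_um = NULL,
                                     cell_density = NULL, method = "otsu",
                                     value = NULL) {
  voxel_um <- voxel_um %||% attr(volume, "voxel_um") %||% rep(1, 3)
  if (!identical(dim(volume), dim(hilus_roi)))
    stop("ROI mask does not fit the volume", call. = FALSE)
  m <- suppressWarnings(threshold_channel(volume, method, value))
  thr <- attr(m, "threshold")
  m <- m & hilus_roi
  lab <- label_components(m)
  n <- attr(lab, "n")
  vox_vol <- prod(voxel_um)
  obj <- if (n > 0) tabulate(lab[lab > 0L], n) * vox_vol else numeric(0)
  summed <- sum(obj)
  roi_vol <- sum(hilus_roi) * vox_vol
  dens <- summed / roi_vol
  structure(list(
    n_objects = n, object_volumes_um3 = obj, summed_volume_um3 = summed,
    roi_volume_um3 = roi_vol, density = dens,
    normalized_density = if (is.null(cell_density)) dens
                         else dens / cell_density,
    normalized = !is.null(cell_density), threshold = thr
  ), class = "septodg_projection")
}
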