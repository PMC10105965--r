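# Thresholding, component labeling, counting, colocalization, densities.

test_that("Otsu separates a bimodal image exactly; degenerate warns", {
  img <- matrix(0, 40, 40)
  img[10:20, 10:20] <- 200
  m <- threshold_channel(img)
  expect_equal(sum(m), 11 * 11)
  expect_true(all(which(m) == which(img == 200)))
  expect_warning(m0 <- threshold_channel(matrix(5, 10, 10)), "constant")
  expect_equal(sum(m0), 0)
  # fixed and percentile methods
  expect_equal(sum(threshold_channel(img, "fixed", value = 100)), 121)
  expect_equal(sum(threshold_channel(img, "percentile", value = 0.99)),
               sum(img > quantile(img, 0.99)))
})

test_that("a painted fraction is recovered within 10% under noise", {
  set.seed(8)
  img <- matrix(rnorm(300 * 300, 10, 5), 300)
  paint <- sample(length(img), round(0.03 * length(img)))
  img[paint] <- 200 + rnorm(length(paint), 0, 5)
  m <- threshold_channel(img)
  frac <- mean(m)
  expect_lt(abs(frac - 0.03) / 0.03, 0.10)
})

test_that("component labeling equals the flood-fill oracle", {
  set.seed(12)
  # 3D volumes up to 32^3 at several densities, plus 2D sections
  for (p in c(0.05, 0.2, 0.4)) {
    mask <- array(runif(32^3) < p, dim = c(32, 32, 32))
    a <- label_components(mask)
    b <- floodfill_labels(mask)
    expect_equal(attr(a, "n"), attr(b, "n"))
    expect_true(same_partition(a, b))
  }
  mask2 <- matrix(runif(64 * 64) < 0.3, 64)
  a2 <- label_components(mask2)
  b2 <- floodfill_labels(mask2)
  expect_equal(attr(a2, "n"), attr(b2, "n"))
  expect_true(same_partition(a2, b2))
  # empty mask
  e <- label_components(array(FALSE, c(4, 4, 4)))
  expect_equal(attr(e, "n"), 0)
})

test_that("summed object volume is invariant under translation", {
  cfg <- quick_cfg(seed = 3, imaging = list(n_processes = 10L))
  sim <- simulate_tracing_volume(cfg, "anterograde_volume")
  pr <- reconstruct_processes_3d(sim$data$volume, sim$rois$hilus)
  # translate the volume (and ROI) by a few voxels with wrap-free padding
  v2 <- sim$data$volume[c(3:dim(sim$data$volume)[1], 1, 2), , ]
  attr(v2, "voxel_um") <- attr(sim$data$volume, "voxel_um")
  r2 <- sim$rois$hilus[c(3:dim(sim$rois$hilus)[1], 1, 2), , ]
  pr2 <- reconstruct_processes_3d(v2, r2,
                                  voxel_um = attr(sim$data$volume,
                                                  "voxel_um"))
  expect_equal(pr2$summed_volume_um3, pr$summed_volume_um3,
               tolerance = 0.02)
  expect_equal(sum(pr$object_volumes_um3), pr$summed_volume_um3)
})

test_that("counting: spheres, empty channels, touching blobs", {
  cfg <- quick_cfg(seed = 6, imaging = list(n_somata = 200L))
  sim <- simulate_tracing_volume(cfg, "anterograde_volume")
  cc <- count_cells(sim$data$ms_image, sim$rois$ms)
  expect_equal(cc$count, sim$truth$n_somata_ms)   # 50 non-touching somata
  expect_equal(cc$density,
               cc$count / (cc$roi_area_um2 * 40))

  empty <- matrix(0, 50, 50)
  cc0 <- count_cells(empty, matrix(TRUE, 50, 50), pixel_um = c(1, 1))
  expect_equal(cc0$count, 0)
  expect_error(count_cells(empty, matrix(FALSE, 50, 50)), "empty ROI")

  # two disks touching at one pixel resolve as two cells
  img <- matrix(0, 40, 60)
  img[septodg:::rasterize_disk(c(40L, 60L), c(1, 1), c(20, 20), 5)] <- 200
  img[septodg:::rasterize_disk(c(40L, 60L), c(1, 1), c(20, 30), 5)] <- 200
  lab <- label_components(threshold_channel(img))
  expect_equal(attr(lab, "n"), 1)                  # merged by touching
  cc2 <- count_cells(img, matrix(TRUE, 40, 60), pixel_um = c(1, 1))
  expect_equal(cc2$count, 2)                       # split by watershed
})

test_that("colocalization fraction: boundaries and recovery", {
  # all somata painted in the GABA channel -> fraction 1
  img <- matrix(0, 60, 60)
  for (cx in c(15, 30, 45))
    img[septodg:::rasterize_disk(c(60L, 60L), c(1, 1), c(30, cx), 5)] <- 200
  cf1 <- colocalization_fraction(img, img, pixel_um = c(1, 1))
  expect_equal(cf1$fraction, 1)
  expect_equal(cf1$n_total, 3)
  # zero GABA channel -> fraction 0
  cf0 <- colocalization_fraction(img, matrix(0, 60, 60), pixel_um = c(1, 1))
  expect_equal(cf0$fraction, 0)
  # no somata -> undefined
  cfu <- colocalization_fraction(matrix(0, 60, 60), img, pixel_um = c(1, 1))
  expect_true(cfu$undefined)

  # generator world: recovered fraction equals the realized Binomial draw
  cfg <- quick_cfg(seed = 9)
  sim <- simulate_tracing_volume(cfg, "retrograde_sections")
  cf <- colocalization_fraction(lapply(sim$data$sections, `[[`, "mcherry"),
                                lapply(sim$data$sections, `[[`, "gaba"),
                                roi = sim$rois$MS, pixel_um = sim$pixel_um)
  expect_equal(cf$n_total, sim$truth$ms_soma_count)
  expect_equal(cf$fraction, sim$truth$coloc_frac_realized, tolerance = 0.04)
})

test_that("connectivity ratio: arithmetic, empty label, ranking recovery", {
  # constructed areas: input 200 um^2 vs starter 100 um^2 -> ratio 2
  sec <- matrix(0, 50, 50)
  sec[1:10, 1:20] <- 200                     # 200 px = 200 um^2 at 1 um px
  rois <- list(MS = matrix(FALSE, 50, 50))
  rois$MS[1:25, 1:25] <- TRUE
  st <- matrix(0, 50, 50)
  st[30:39, 30:39] <- 200                    # 100 px
  st_roi <- matrix(FALSE, 50, 50); st_roi[26:50, 26:50] <- TRUE
  cr <- connectivity_ratio(list(sec), rois, st, st_roi, pixel_um = c(1, 1),
                           method = "fixed", value = 100)
  expect_equal(cr$ranking$ratio, 2)
  expect_equal(cr$starter_area_um2, 100)

  # no input label anywhere -> all ratios 0
  cr0 <- connectivity_ratio(list(matrix(0, 50, 50)), rois, st, st_roi,
                            pixel_um = c(1, 1), method = "fixed", value = 100)
  expect_equal(cr0$ranking$ratio, 0)

  # zero starter area -> undefined, flagged
  cru <- connectivity_ratio(list(sec), rois, matrix(0, 50, 50), st_roi,
                            pixel_um = c(1, 1), method = "fixed", value = 100)
  expect_true(cru$undefined)

  # generator ranking: MS and DB are the top-2 regions across seeds
  for (s in 1:3) {
    cfg <- quick_cfg(seed = 50 + s)
    sim <- simulate_tracing_volume(cfg, "retrograde_sections")
    cr <- connectivity_ratio(lapply(sim$data$sections, `[[`, "mcherry"),
                             sim$rois[names(sim$rois) != "starter_DG"],
                             sim$data$starter_image, sim$rois$starter_DG,
                             pixel_um = sim$pixel_um)
    expect_equal(sort(cr$ranking$region[1:2]), c("DB", "MS"))
  }
})

test_that("3D reconstruction: capsule volume, empties, section doubling", {
  # empty volume
  pr0 <- reconstruct_processes_3d(array(0, c(10, 10, 10)),
                                  array(TRUE, c(10, 10, 10)),
                                  voxel_um = c(1, 1, 1),
                                  method = "fixed", value = 50)
  expect_equal(pr0$n_objects, 0)
  expect_equal(pr0$density, 0)

  # single capsule, 0.5 um voxels: one object, volume within 10% of
  # pi r^2 L + sphere caps
  vx <- 0.5
  dims <- as.integer(c(120, 20, 20))
  vol <- array(0, dims)
  vol[septodg:::rasterize_capsule(dims, rep(vx, 3), c(5, 5, 5),
                                  c(55, 5, 5), 1)] <- 200
  attr(vol, "voxel_um") <- rep(vx, 3)
  pr <- reconstruct_processes_3d(vol, array(TRUE, dims),
                                 method = "fixed", value = 50)
  analytic <- pi * 50 + 4 / 3 * pi
  expect_equal(pr$n_objects, 1)
  expect_lt(abs(pr$summed_volume_um3 - analytic) / analytic, 0.10)

  # duplicating every section leaves the density invariant
  vol2 <- array(c(vol, vol), c(dims[1] * 2, dims[2], dims[3]))
  vol2[] <- rep(vol, 2)  # stack two copies along z
  roi2 <- array(TRUE, dim(vol2))
  pr2 <- reconstruct_processes_3d(vol2, roi2, voxel_um = rep(vx, 3),
                                  method = "fixed", value = 50)
  expect_equal(pr2$density, pr$density, tolerance = 1e-9)

  expect_error(reconstruct_processes_3d(vol, array(TRUE, c(2, 2, 2))),
               "fit")
})

test_that("doubling process count doubles normalized projection density", {
  ratio <- vapply(1:5, function(s) {
    dens <- vapply(c(15L, 30L), function(np) {
      cfg <- quick_cfg(seed = 900 + s, imaging = list(n_processes = np))
      sim <- simulate_tracing_volume(cfg, "anterograde_volume",
                                     seed = child_seed(900 + s,
                                                       paste0("v", np)))
      cc <- count_cells(sim$data$ms_image, sim$rois$ms)
      reconstruct_processes_3d(sim$data$volume, sim$rois$hilus,
                               cell_density = cc$density)$normalized_density
    }, numeric(1))
    dens[2] / dens[1]
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 2), 0.2)
})
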