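test_that("adaptive Canny finds rings and step edges, and ignores flat slices", {
  # constant slice: no gradients, empty edge map
  expect_equal(sum(canny_slice(matrix(0.4, 32, 32))), 0)
  expect_error(canny_slice(matrix(0, 2, 2)))

  # filled bright disk: ~1-px ring with about 2*pi*r edge pixels
  m <- matrix(0.05, 64, 64)
  rr <- row(m); cc <- col(m)
  r_disk <- 14
  m[(rr - 32)^2 + (cc - 32)^2 <= r_disk^2] <- 0.9
  e <- canny_slice(m)
  n_edge <- sum(e)
  expect_lt(abs(n_edge - 2 * pi * r_disk) / (2 * pi * r_disk), 0.2)
  # edge pixels hug the disk boundary (Gaussian smoothing spreads ~1 px)
  d_ring <- abs(sqrt((rr[e] - 32)^2 + (cc[e] - 32)^2) - r_disk)
  expect_lt(max(d_ring), 3.5)

  # vertical step down one column: edges confined to that column +/- 1
  s <- matrix(0.1, 32, 32)
  s[, 17:32] <- 0.6
  es <- canny_slice(s)
  expect_gt(sum(es), 0)
  expect_true(all(col(es)[es] %in% 15:18))
})

test_that("the Hough search recovers two clean ellipses and fails on one", {
  ring1 <- raster_ellipse_ring(64, 64, 20, 32, 9, 15)
  ring2 <- raster_ellipse_ring(64, 64, 45, 32, 9, 15)
  ells <- hough_two_ellipses(ring1 | ring2, a_range = c(5, 12), b_range = c(8, 20))
  cents <- vapply(ells, function(e) c(e$cx, e$cy), numeric(2))
  expect_lt(max(abs(cents[, 1] - c(20, 32))), 2)
  expect_lt(max(abs(cents[, 2] - c(45, 32))), 2)
  expect_equal(ells[[1]]$a, 9, tolerance = 1)
  expect_equal(ells[[1]]$b, 15, tolerance = 1)

  expect_error(hough_two_ellipses(ring1, a_range = c(5, 12), b_range = c(8, 20)),
               "fewer than two")

  # 5% salt noise: still within 3 px
  withr::with_seed(2, {
    noisy <- (ring1 | ring2)
    salt <- matrix(runif(64 * 64) < 0.05, 64, 64)
    noisy <- noisy | salt
  })
  ells_n <- hough_two_ellipses(noisy, a_range = c(5, 12), b_range = c(8, 20))
  cents_n <- vapply(ells_n, function(e) c(e$cx, e$cy), numeric(2))
  expect_lt(max(abs(cents_n[, 1] - c(20, 32))), 3)
  expect_lt(max(abs(cents_n[, 2] - c(45, 32))), 3)
})

test_that("contour closure fills ellipse interiors and bridges small gaps", {
  # large, clearly separated ellipses so the 1-px ring layer stays < 5%
  ring1 <- raster_ellipse_ring(96, 96, 24, 48, 20, 34)
  ring2 <- raster_ellipse_ring(96, 96, 72, 48, 20, 34)
  ells <- hough_two_ellipses(ring1 | ring2, a_range = c(16, 24), b_range = c(30, 38))
  regions <- close_lung_contours(ring1 | ring2, ells)
  for (k in 1:2) {
    area <- sum(regions[[k]])
    expect_lt(abs(area - pi * 20 * 34) / (pi * 20 * 34), 0.05)
  }
  # interiors are filled (center pixel set)
  expect_true(regions[[1]][ells[[1]]$cx, ells[[1]]$cy])

  # a 3-pixel gap in one ring is bridged and still filled
  gap_ring <- ring1
  gap_ring[4:6, 48] <- FALSE # cut near the left apex
  regions_g <- close_lung_contours(gap_ring | ring2, ells)
  expect_gt(sum(regions_g[[1]]), 0.9 * pi * 20 * 34)
})

test_that("3D reconstruction stacks slices, interpolates failures, and smooths mildly", {
  nr <- 32; nc <- 32; nz <- 16
  disk <- matrix(FALSE, nr, nc)
  disk[(row(disk) - 16)^2 + (col(disk) - 16)^2 <= 64] <- TRUE
  slices <- rep(list(disk), nz)
  lm <- reconstruct_lung_mask(slices, c(nr, nc, nz))
  # identical slices: an elliptic cylinder; smoothing changes < 2% of voxels
  stack <- array(rep(disk, nz), c(nr, nc, nz))
  expect_lt(mean(lm$mask != stack), 0.02)

  # failed slices are interpolated from neighbors (with a message)
  slices2 <- slices
  slices2[8] <- list(NULL)
  expect_message(lm2 <- reconstruct_lung_mask(slices2, c(nr, nc, nz)),
                 "interpolating")
  expect_gt(sum(lm2$mask[, , 8]), 0.9 * sum(disk))

  # single slice: within-slice smoothing only, no z bleed
  lm1 <- reconstruct_lung_mask(list(disk), c(nr, nc, 1))
  expect_equal(dim(lm1$mask), c(nr, nc, 1))
  expect_gt(sum(lm1$mask), 0.9 * sum(disk))
})

test_that("primary tumor detection passes through manual tags and recovers phantom spheres", {
  manual <- tumor_spec(c(10, 20, 30), 7)
  vol <- volume_image(array(0.1, c(16, 16, 16)))
  expect_identical(detect_primary_tumor(vol, manual = manual), manual)

  expect_error(detect_primary_tumor(volume_image(array(0, c(16, 16, 16)))),
               "no tumor found")

  # noise-free phantom with a 5 mm tumor: recovered within 1 voxel spacing
  lungs <- lungmetmap:::default_lungs(c(64, 64, 64), c(1, 1, 1))
  tum <- tumor_spec(lungs[[2]]$center, 5)
  ph <- generate_phantom(phantom_spec(noise_sd = 0, seed = 6, tumor = tum))
  est <- detect_primary_tumor(ph$volume)
  expect_lt(max(abs(est$location - tum$location)), 1.5)
  expect_lt(abs(est$size - 5), 1)
})

test_that("full lung segmentation reaches high Dice on noise-free phantoms", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0, seed = 11))
  lm <- segment_lungs(ph$volume)
  expect_setequal(unique(as.vector(lm$mask)), c(0L, 1L))
  expect_equal(dim(lm$mask), dim(ph$volume$data))
  d <- dice_coefficient(lm$mask, ph$truth$lung_mask)
  expect_gte(d, 0.90)
  # determinism of the full per-slice pipeline
  lm2 <- segment_lungs(ph$volume)
  expect_identical(lm$mask, lm2$mask)
  # per-slice provenance covers the slices that intersect the lungs
  expect_gt(nrow(lm$ellipses), 30)
  expect_true(all(lm$ellipses$score >= 0.5))
})
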