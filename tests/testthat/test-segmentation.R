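test_that("3D median filter matches a brute-force neighbourhood oracle", {
  const <- array(7, c(4, 4, 4))
  expect_equal(median_filter3d(const, 1), const)

  imp <- array(0, c(5, 5, 5)); imp[3, 3, 3] <- 100
  expect_equal(median_filter3d(imp, 1), array(0, c(5, 5, 5)))

  step <- array(rep(c(0, 0, 10, 10, 10), each = 25), c(5, 5, 5))  # step along x
  filt <- median_filter3d(step, 1)
  expect_equal(filt, oracle_median3d(step, 1))
  # the step edge stays between x=2 and x=3
  expect_true(all(filt[, , 1:2] == 0) && all(filt[, , 3:5] == 10))

  set.seed(21)
  noisy <- array(sample(0:50, 5^3, TRUE), c(5, 5, 5))
  expect_equal(median_filter3d(noisy, 1), oracle_median3d(noisy, 1))
  expect_equal(median_filter3d(noisy, 2), oracle_median3d(noisy, 2))

  expect_error(median_filter3d(noisy, 0), "radius")
  expect_error(median_filter3d(noisy, 5), "radius")
})

two_cube_volume <- function() {
  vol <- array(0, c(10, 12, 14))
  vol[2:4, 2:5, 2:4] <- 100      # 3 x 4 x 3 = 36 voxels
  vol[7:9, 8:11, 9:13] <- 100    # 3 x 4 x 5 = 60 voxels
  vol
}

test_that("threshold + 26-connectivity finds separated objects exactly", {
  vol <- two_cube_volume()
  lab <- segment_objects(vol, threshold = 50, voxel_dims = c(2, 0.5, 0.5))
  stats <- object_volume(lab)
  expect_equal(nrow(stats), 2)
  expect_equal(stats$voxel_count, c(60, 36))  # sorted by decreasing size
  expect_equal(stats$volume_um3, c(60, 36) * 0.5)

  expect_message(empty <- segment_objects(vol, threshold = 1000), "empty")
  expect_equal(nrow(object_volume(empty)), 0)

  # min_voxels filters the small cube out
  lab2 <- segment_objects(vol, threshold = 50, min_voxels = 50)
  expect_equal(object_volume(lab2)$voxel_count, 60)

  # Otsu lands between the two modes
  expect_equal(object_volume(segment_objects(vol))$voxel_count, c(60, 36))

  # diagonal touch merges under 26-connectivity
  diag2 <- array(0, c(3, 3, 3)); diag2[1, 1, 1] <- 1; diag2[2, 2, 2] <- 1
  expect_equal(nrow(object_volume(segment_objects(diag2, threshold = 0.5))), 1)
})

test_that("object volume follows voxel_count x voxel size", {
  lab <- array(0L, c(5, 5, 5)); lab[1:4, 1:5, 1:5] <- 1L
  lv <- labeled_volume(lab, voxel_dims = c(2, 0.5, 0.5))
  expect_equal(object_volume(lv)$voxel_count, 100)
  expect_equal(object_volume(lv)$volume_um3, 50)

  # digitised sphere of radius 5 voxels vs continuous volume
  g <- 13; c0 <- 7
  idx <- as.matrix(expand.grid(1:g, 1:g, 1:g))
  sphere <- array(as.integer(rowSums((idx - c0)^2) <= 25), c(g, g, g))
  lv2 <- labeled_volume(sphere, voxel_dims = c(1, 1, 1))
  expect_lt(abs(object_volume(lv2)$volume_um3 - 4 / 3 * pi * 125),
            0.15 * 4 / 3 * pi * 125)
})

test_that("fluorescence integration equals brute-force masked sums", {
  set.seed(13)
  vol <- two_cube_volume() + array(sample(0:5, 10 * 12 * 14, TRUE), c(10, 12, 14))
  lab <- segment_objects(two_cube_volume(), threshold = 50,
                         voxel_dims = c(2, 0.5, 0.5))
  st <- integrate_fluorescence(lab, vol)
  for (l in st$label) {
    s <- 0; n <- 0
    for (z in 1:10) for (y in 1:12) for (x in 1:14)
      if (lab$labels[z, y, x] == l) { s <- s + vol[z, y, x]; n <- n + 1 }
    expect_equal(st$integrated_fluorescence[st$label == l], s)
    expect_equal(st$mean_fluorescence[st$label == l], s / n)
  }
  # union of all labels equals the masked whole-volume sum
  expect_equal(sum(st$integrated_fluorescence), sum(vol[lab$labels > 0]))
  expect_error(integrate_fluorescence(lab, vol[1:5, , ]), "geometry")

  tiny <- array(0, c(3, 3, 3)); tiny[1:2, 1, 1] <- 1
  lv <- segment_objects(tiny, threshold = 0.5)
  st2 <- integrate_fluorescence(lv, array(7, c(3, 3, 3)))
  expect_equal(st2$integrated_fluorescence, 14)
  expect_equal(st2$mean_fluorescence, 7)
})

test_that("segmentation recovers simulator plastids and their volumes", {
  tl <- build_timeline(1, 0, 0, 60)
  params <- scene_params(plastids_per_cell = 4, motion_step = 0, seed = 5)
  sc <- render_scene(params, tl)
  frame <- sc$stack$intensities[1, , , ]
  # noise-free, so no median filter (it would erode along the coarse z axis);
  # half-maximum threshold: blob intensity at the nominal radius
  thr <- params$background$level + params$Fm_amplitude / 2
  lab <- segment_objects(frame, threshold = thr, min_voxels = 5,
                         voxel_dims = c(2, 0.5, 0.5))
  stats <- object_volume(lab)
  expect_equal(nrow(stats), 4)
  truth <- sc$truth$volumes
  expect_equal(sum(stats$voxel_count), sum(truth$voxel_count),
               tolerance = 0.10)
})

test_that("area fraction is the plastid share of the cell section", {
  cell <- matrix(TRUE, 10, 10)
  expect_equal(area_fraction(cell, cell), 100)
  quarter <- matrix(FALSE, 10, 10); quarter[1:5, 1:5] <- TRUE
  expect_equal(area_fraction(cell, quarter), 25)
  expect_equal(area_fraction(cell, matrix(FALSE, 10, 10)), 0)
  expect_error(area_fraction(matrix(FALSE, 10, 10), quarter), "empty")
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  outside <- matrix(FALSE, 10, 10); outside[, 6] <- TRUE
  expect_error(area_fraction(half, outside), "outside")
})
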