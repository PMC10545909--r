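KIN <- list(NPQmax = 2, tau_ind = 90, tau_rel = 120,
            transient_amp = 0, transient_tau = 60)

test_that("kinetic forward model has the right limits and closed form", {
  expect_equal(npq_kinetics(0, "actinic", KIN), 0)
  expect_equal(npq_kinetics(1e9, "actinic", KIN), 2)
  expect_equal(npq_kinetics(90, "actinic", KIN), 2 * (1 - exp(-1)))
  expect_equal(round(npq_kinetics(90, "actinic", KIN), 3), 1.264)
  expect_equal(npq_kinetics(0, "dark_reference", KIN), 0)
  expect_equal(npq_kinetics(120, "relaxation", KIN, npq_at_light_off = 1.5),
               1.5 * exp(-1))
  expect_error(npq_kinetics(10, "relaxation", KIN), "npq_at_light_off")
  expect_error(npq_kinetics(-1, "actinic", KIN), ">= 0")

  # transient term peaks at tau and adds amp * 1 there
  kin_tr <- modifyList(KIN, list(NPQmax = 0.3, transient_amp = 1.2))
  tt <- seq(0, 600, by = 5)
  v <- npq_kinetics(tt, "actinic", kin_tr)
  expect_equal(tt[which.max(v)], 60, tolerance = 10)
})

test_that("per-frame true NPQ follows the protocol phases continuously", {
  tl <- default_timeline()
  v <- npq_true_series(tl, KIN)
  expect_equal(v[1:3], rep(0, 3))                       # dark-adapted start
  expect_equal(v[4], 0)                                 # light-on at frame 4
  expect_equal(v[9], 2 * (1 - exp(-300 / 90)))
  expect_equal(v[10], 2 * (1 - exp(-360 / 90)))         # continuous at light-off
  expect_equal(v[11] / v[10], exp(-60 / 120))
})

test_that("rendering is deterministic and follows the fluorescence law", {
  tl <- default_timeline()
  p <- scene_params(noise = list(poisson = TRUE, gaussian_sd = 5), seed = 42)
  s1 <- render_scene(p, tl)
  s2 <- render_scene(p, tl)
  expect_identical(s1$stack$intensities, s2$stack$intensities)
  expect_identical(s1$truth$trajectories, s2$truth$trajectories)
  s3 <- render_scene(scene_params(noise = list(poisson = TRUE, gaussian_sd = 5),
                                  seed = 43), tl)
  expect_false(identical(s1$stack$intensities, s3$stack$intensities))

  # NPQmax = 0, no noise, no motion: all frames differ only by background
  p0 <- scene_params(kinetics = list(NPQmax = 0), motion_step = 0,
                     background = list(actinic_step = 0))
  s0 <- render_scene(p0, tl)
  for (t in 2:15)
    expect_equal(s0$stack$intensities[t, , , ], s0$stack$intensities[1, , , ])

  # steady light with NPQmax = 1 halves the plastid signal (Fm' = Fm / 2)
  p1 <- scene_params(kinetics = list(NPQmax = 1, tau_ind = 1e-6),
                     motion_step = 0)
  s1b <- render_scene(p1, tl)
  bgmask <- truth_background_roi(s1b$truth)$mask
  cellmask <- truth_cell_roi(s1b$truth, 1)$mask
  pr <- sum_project(s1b$stack)
  sig <- function(t) mean(pr$intensities[t, , ][cellmask]) -
    mean(pr$intensities[t, , ][bgmask])
  expect_equal(sig(9) / sig(1), 0.5, tolerance = 1e-9)
})

test_that("ground truth is consistent with the rendered scene", {
  tl <- default_timeline()
  sc <- render_scene(scene_params(n_cells = 2, plastids_per_cell = 4,
                                  grid = c(z = 14, y = 64, x = 96)), tl)
  tr <- sc$truth
  expect_equal(tr$npq$npq_true[1], 0)  # dark-adapted start
  expect_equal(nrow(tr$volumes), 8)
  expect_equal(length(tr$area_frac), 2)
  expect_true(all(tr$area_frac > 0 & tr$area_frac < 100))
  # trajectories stay inside their cell boxes
  for (p in 1:8) {
    b <- tr$cells[tr$plastids$cell[p], ]
    expect_true(all(tr$trajectories[, p, 2] >= b$y0 &
                    tr$trajectories[, p, 2] <= b$y1))
    expect_true(all(tr$trajectories[, p, 3] >= b$x0 &
                    tr$trajectories[, p, 3] <= b$x1))
  }
  # truth label masks match digitised sphere counts
  lv <- truth_plastid_labels(tr, 1)
  expect_equal(object_volume(lv)$voxel_count[order(-object_volume(lv)$voxel_count)],
               sort(tr$volumes$voxel_count, decreasing = TRUE),
               tolerance = 0)
  # background strip really is empty: dark-frame strip equals the offset
  expect_equal(unique(as.vector(sc$stack$intensities[1, , 1:16, ])), 50)
})

test_that("oversized plastid complements are rejected", {
  expect_error(render_scene(scene_params(plastid_radius = 8),
                            default_timeline()), "cannot fit")
  expect_error(render_scene(scene_params(plastids_per_cell = 100),
                            default_timeline()), "cannot fit")
})

test_that("recovery reports quantify bias and RMSE", {
  est <- data.frame(id = 1:4, value = c(1, 2, 3, 4))
  tru <- data.frame(id = 1:4, value = c(1, 2, 3, 4))
  r <- recovery_report(est, tru)
  expect_equal(r$bias, 0)
  expect_equal(r$rmse, 0)

  est2 <- data.frame(id = 1:4, value = c(1, 2, 3, 4) + 0.1)
  r2 <- recovery_report(est2, tru)
  expect_equal(r2$bias, 0.1)
  expect_equal(r2$rmse, 0.1)
  expect_equal(r2$table$rel_error, 0.1 / c(1, 2, 3, 4))

  expect_error(recovery_report(data.frame(id = 1:3, value = 1:3), tru),
               "unmatched")
})

test_that("noise-free end-to-end NPQmax recovery is within 1 percent", {
  tl <- default_timeline()
  rec <- run_npq_recovery(scene_params(seed = 9), tl)
  est <- extract_features(rec$npq, tl)
  true_max <- max(rec$truth$npq$npq_true[rec$truth$npq$phase == "actinic"])
  expect_equal(est$NPQmax, true_max, tolerance = 0.01)
})
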