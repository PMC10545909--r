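test_that("Y = (Fm - F')/Fm from pre-pulse mean and pulse maximum", {
  tr <- corrected_trace(c(100, 100, 100, 100, 400))
  got <- compute_Y(tr, pulse_frames = 5)
  expect_equal(got$F_prime, 100)
  expect_equal(got$Fm, 400)
  expect_equal(got$Y, 0.75)

  # saturated measuring light: F' reaches Fm, Y = 0
  flat <- corrected_trace(c(400, 400, 400, 400, 400))
  expect_equal(compute_Y(flat, pulse_frames = 5)$Y, 0)

  # multiple pulse frames: Fm is their maximum
  multi <- corrected_trace(c(100, 120, 390, 410, 405))
  expect_equal(compute_Y(multi, pulse_frames = 3:5, pre_frames = 1:2)$Y,
               (410 - 110) / 410)

  expect_error(compute_Y(corrected_trace(rep(0, 5)), pulse_frames = 5),
               "Fm <= 0")
  over <- corrected_trace(c(500, 500, 400))
  expect_warning(y <- compute_Y(over, pulse_frames = 3)$Y, "negative")
  expect_lt(y, 0)
})

test_that("NPQ series uses the dark-reference mean as Fm", {
  tl <- build_timeline(3, 1, 0, 60)
  tr <- corrected_trace(c(400, 400, 400, 200), tl$frames$timestamp)
  got <- compute_npq_series(tr, tl)
  expect_equal(got$Fm_dark, 400)
  expect_equal(got$npq$npq, 1.0)

  # unequal dark frames: the mean (not max) is the reference
  tr2 <- corrected_trace(c(380, 400, 420, 200), tl$frames$timestamp)
  expect_equal(compute_npq_series(tr2, tl)$npq$npq, (400 - 200) / 200)

  # F == Fm_dark -> no quenching
  tr3 <- corrected_trace(c(400, 400, 400, 400), tl$frames$timestamp)
  expect_equal(compute_npq_series(tr3, tl)$npq$npq, 0)

  # F <= 0 marked undefined, not dropped
  tl2 <- build_timeline(3, 2, 0, 60)
  tr4 <- fluor_trace("c", c(400, 400, 400, -5, 200), tl2$frames$timestamp,
                     background_corrected = TRUE)
  expect_message(got4 <- compute_npq_series(tr4, tl2), "undefined")
  expect_equal(nrow(got4$npq), 2)
  expect_true(is.na(got4$npq$npq[1]))
  expect_equal(got4$npq$npq[2], 1)

  expect_error(compute_npq_series(corrected_trace(c(0, 0, 0, 1),
                                                  tl$frames$timestamp), tl),
               "Fm_dark")
})

test_that("PSII yield quotient and its edge cases", {
  expect_equal(compute_phi_psii(100, 400), 0.75)
  expect_equal(compute_phi_psii(400, 400), 0)
  expect_equal(compute_phi_psii(0, 400), 1)
  expect_warning(phi <- compute_phi_psii(500, 400), "negative")
  expect_equal(phi, -0.25)
  expect_error(compute_phi_psii(100, 0), "Fm_pulse")
})

test_that("kinetic features reproduce closed-form least-squares slopes", {
  tl <- default_timeline()
  # constant NPQ in the light: NPQav = NPQmax = c, zero induction slope
  npq_df <- data.frame(frame = 4:15, timestamp = tl$frames$timestamp[4:15],
                       phase = tl$frames$phase[4:15], F = 100,
                       npq = c(rep(0.8, 6), rep(0.1, 6)))
  f <- extract_features(list(Fm_dark = 400, npq = npq_df), tl, area_frac = 25)
  expect_equal(f$NPQav, 0.8)
  expect_equal(f$NPQmax, 0.8)
  expect_equal(f$Induction, 0)
  expect_equal(f$Fmax, 400)
  expect_equal(f$AreaFrac, 25)

  # hand-computed OLS slopes on the 2-min windows (0/60/120 s points)
  npq_df$npq <- c(0, 0.5, 1.0, 1.0, 1.0, 1.0, 1.0, 0.6, 0.2, 0.2, 0.2, 0.2)
  f2 <- extract_features(list(Fm_dark = 400, npq = npq_df), tl)
  expect_equal(f2$Induction, 0.5)   # min^-1
  expect_equal(f2$Decay, -0.4)      # min^-1

  # window boundary is inclusive at exactly 120 s
  tl30 <- build_timeline(3, 6, 6, 30)
  npq30 <- data.frame(frame = 4:15, timestamp = tl30$frames$timestamp[4:15],
                      phase = tl30$frames$phase[4:15], F = 100,
                      npq = c(seq(0, 1, length.out = 5), 1, rep(0.2, 6)))
  f3 <- extract_features(list(Fm_dark = 1, npq = npq30), tl30)
  # 5 points at 0,30,...,120 s with slope 0.25/30 s = 0.5 min^-1
  expect_equal(f3$Induction, 0.5)
})

test_that("degenerate protocols yield NA features, never zeros", {
  tl <- build_timeline(3, 0, 6, 60)
  npq_df <- data.frame(frame = 4:9, timestamp = tl$frames$timestamp[4:9],
                       phase = tl$frames$phase[4:9], F = 100, npq = 0.5)
  f <- extract_features(list(Fm_dark = 400, npq = npq_df), tl)
  expect_true(is.na(f$NPQav) && is.na(f$NPQmax) && is.na(f$Induction))
  expect_equal(f$Decay, 0)

  tl1 <- build_timeline(3, 1, 0, 60)
  npq1 <- data.frame(frame = 4, timestamp = tl1$frames$timestamp[4],
                     phase = "actinic", F = 100, npq = 0.7)
  f1 <- extract_features(list(Fm_dark = 400, npq = npq1), tl1)
  expect_equal(f1$NPQmax, 0.7)
  expect_true(is.na(f1$Induction))  # < 2 window points: slope undefined
})

test_that("Y, NPQ and features except Fmax are scale invariant", {
  tl <- default_timeline()
  set.seed(9)
  vals <- c(400, 410, 390, 150, 140, 130, 125, 120, 118, 200, 260, 300, 330, 350, 360)
  tr <- corrected_trace(vals, tl$frames$timestamp)
  for (k in c(0.5, 3, 17)) {
    trk <- corrected_trace(k * vals, tl$frames$timestamp)
    n1 <- compute_npq_series(tr, tl); nk <- compute_npq_series(trk, tl)
    expect_equal(nk$npq$npq, n1$npq$npq)
    f1 <- extract_features(n1, tl, area_frac = 30)
    fk <- extract_features(nk, tl, area_frac = 30)
    expect_equal(fk[c("NPQav", "NPQmax", "Induction", "Decay", "AreaFrac")],
                 f1[c("NPQav", "NPQmax", "Induction", "Decay", "AreaFrac")])
    expect_equal(fk$Fmax, k * f1$Fmax)
    expect_equal(compute_Y(trk, pulse_frames = 2)$Y,
                 compute_Y(tr, pulse_frames = 2)$Y)
  }
})

test_that("npq kinetics are inverted exactly on noise-free static scenes", {
  tl <- default_timeline()
  params <- scene_params(motion_step = 0,
                         kinetics = list(NPQmax = 2, tau_ind = 90, tau_rel = 120))
  rec <- run_npq_recovery(params, tl)
  cmp <- merge(rec$npq$npq, rec$truth$npq, by = "frame")
  expect_equal(cmp$npq, cmp$npq_true, tolerance = 1e-9)
  # plateau of a fast-inducing scene recovers NPQmax itself
  fast <- scene_params(motion_step = 0, kinetics = list(NPQmax = 2, tau_ind = 1))
  rec2 <- run_npq_recovery(fast, tl)
  light <- rec2$npq$npq[rec2$npq$npq$phase == "actinic", ]
  expect_equal(max(light$npq), 2, tolerance = 1e-6)
})
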