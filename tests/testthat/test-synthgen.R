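test_that("identical seeds yield identical cohorts", {
  c1 <- generateCohort(tinyConfig(seed = 11), n_per_group = 3)
  c2 <- generateCohort(tinyConfig(seed = 11), n_per_group = 3)
  expect_identical(cohortTruth(c1), cohortTruth(c2))
  expect_identical(cohortAnimals(c1)[[2]]@vessels,
                   cohortAnimals(c2)[[2]]@vessels)
  expect_identical(cohortAnimals(c1)[[1]]@traces[[1]]@signal,
                   cohortAnimals(c2)[[1]]@traces[[1]]@signal)
  c3 <- generateCohort(tinyConfig(seed = 12), n_per_group = 3)
  expect_false(identical(cohortTruth(c1)$v_v, cohortTruth(c3)$v_v))
})

test_that("zero-variance calibrations collapse every animal onto the group means", {
  tt <- generateTruthTable(degenerateConfig(), n_per_group = 3)
  cal <- degenerateCalibrations()[[1]]
  for (m in drawnMetrics()) {
    expect_equal(tt[[m]][tt$group == "WT"], rep(cal@means[[m]], 3),
                 tolerance = 1e-6)
  }
})

test_that("group sample moments converge to the calibration at large n", {
  tt <- generateTruthTable(cohortConfig(seed = 2), n_per_group = 10000)
  cals <- defaultCalibrations()
  for (g in names(cals)) {
    gt <- tt[tt$group == g, ]
    for (m in drawnMetrics()) {
      expect_lt(abs(mean(gt[[m]]) - cals[[g]]@means[[m]]) /
                  cals[[g]]@means[[m]], 0.01)
      expect_lt(abs(sd(gt[[m]]) - cals[[g]]@sds[[m]]) /
                  cals[[g]]@sds[[m]], 0.02)
    }
    # strictly positive draws even for low-mean metrics
    expect_true(all(gt$o2v > 0))
  }
  # the velocity example: sample mean within 1% of 10.5 mm/s
  expect_lt(abs(mean(tt$v_v[tt$group == "WT"]) - 10.5) / 10.5, 0.01)
})

test_that("pooled correlations match the configured targets at large n", {
  tt <- generateTruthTable(cohortConfig(seed = 3), n_per_group = 5000)
  # Fisher CI at this n is +- ~0.02; allow 3x
  expect_lt(abs(cor(tt$o2a, tt$v_v) - (-0.57)), 0.06)
  expect_lt(abs(cor(tt$o2a, tt$nfl_rgcl) - (-0.53)), 0.06)
  # the arteriovenous-difference SD calibration keeps o2av narrow and
  # essentially positive
  expect_lt(sd(tt$o2av[tt$group == "WT"]), 1.6)
  expect_lt(mean(tt$o2av < 0), 0.02)
})

test_that("within-group correlation calibration solves the pooled target", {
  cals <- defaultCalibrations()
  w <- calibrateWithinGroupCorrelation(-0.57, cals, "o2a", "v_v")
  expect_equal(pooledCorrelation(w, cals, "o2a", "v_v"), -0.57,
               tolerance = 1e-9)
  # unattainable target is rejected with a message
  expect_error(calibrateWithinGroupCorrelation(-0.999, cals, "o2a", "v_v"),
               "unattainable")
})

test_that("an infeasible correlation structure is rejected", {
  # a tiny o2av SD would need corr(o2a, o2v) > 1
  cfg <- cohortConfig(o2av_sd = 0.05, seed = 1)
  expect_error(generateTruthTable(cfg, n_per_group = 2), "incompatible")
})

test_that("phase trace forward model matches the closed form", {
  cst <- default_cst
  # zero-quencher limit: tau = tau0
  tr0 <- synthesizePhaseTrace(0, constants = cst)
  expect_equal(estimateLifetime(tr0), tau0(cst), tolerance = 1e-9)
  # po2 = 30 mmHg: phase = arctan(2 pi f tau0 / (1 + kq tau0 po2)),
  # evaluated independently by hand-arithmetic
  f <- 1000
  tau_hand <- 637e-6 / (1 + 381 * 637e-6 * 30)
  phase_hand <- atan(2 * pi * f * tau_hand)
  tr <- synthesizePhaseTrace(30, modulation_frequency_hz = f,
                             constants = cst)
  w <- 2 * pi * f * tr@timeS
  beta <- qr.coef(qr(cbind(1, cos(w), sin(w))), tr@signal)
  expect_equal(atan2(beta[[3]], beta[[2]]), phase_hand, tolerance = 1e-9)
})

test_that("microsphere tracks advance by velocity/frame_rate", {
  set.seed(7)
  # 10.4 mm/s at 104 Hz is exactly 100 um per frame
  trks <- synthesizeTracks(10.4, n_spheres = 5, frame_rate_hz = 104,
                           noise_sd_um = 0, n_frames = 8)
  for (tk in trks) {
    step <- sqrt(diff(tk@xUm)^2 + diff(tk@yUm)^2)
    expect_equal(step, rep(100, 7), tolerance = 1e-9)
  }
  expect_identical(synthesizeTracks(5, n_spheres = 0), list())
  # noiseless tracks invert exactly through the velocimetry chain
  expect_equal(veinVelocity(synthesizeTracks(6.6, n_spheres = 4,
                                             frame_rate_hz = 104,
                                             noise_sd_um = 0)),
               6.6, tolerance = 1e-9)
})

test_that("jittered tracks give an unbiased velocity within Monte-Carlo CI", {
  set.seed(99)
  v <- replicate(800, trackVelocity(
    synthesizeTracks(6.6, n_spheres = 1, frame_rate_hz = 104,
                     noise_sd_um = 1, n_frames = 12)[[1]]))
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 6.6), 3 * se + 1e-9)
})

test_that("caliber profiles have FWHM equal to the true diameter", {
  # pixel-limited (no blur): exact for arbitrary sub-pixel offsets
  for (off in c(0, 0.23, -0.41)) {
    pr <- synthesizeCaliberProfile(30, blur_sd_um = 0,
                                   center_offset_um = off)
    expect_equal(profileDiameter(pr), 30, tolerance = 1e-9)
  }
  pr <- synthesizeCaliberProfile(27.37, blur_sd_um = 0,
                                 center_offset_um = 0.11)
  expect_equal(profileDiameter(pr), 27.37, tolerance = 1e-9)
  # sub-resolution vessels are rejected
  expect_error(synthesizeCaliberProfile(1.5, pixel_pitch_um = 1),
               "two pixel pitches")
})

test_that("blurred noisy profiles recover the diameter to sub-micron accuracy", {
  set.seed(5)
  d <- replicate(400, profileDiameter(
    synthesizeCaliberProfile(30, blur_sd_um = 2, noise_frac = 0.01)))
  expect_lt(abs(mean(d) - 30), 0.5)
})

test_that("layer boundaries are strictly increasing and start at zero", {
  coh <- generateCohort(tinyConfig(seed = 6), n_per_group = 2)
  for (a in cohortAnimals(coh)) {
    expect_equal(a@boundariesNasal[1], 0)
    expect_true(all(diff(a@boundariesNasal) > 0))
    expect_true(all(diff(a@boundariesTemporal) > 0))
    expect_length(a@vessels$vessel_id[a@vessels$type == "vein"], 4L)
  }
})
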