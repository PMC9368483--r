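mkTrack <- function(x, y, fps = 104) {
  new("MicrosphereTrack", trackId = "t", veinId = "v",
      frameIndex = seq_along(x), xUm = x, yUm = y, frameRateHz = fps)
}

test_that("track velocity equals displacement over time", {
  # 100 um per frame at 104 Hz = 10.4 mm/s
  expect_equal(trackVelocity(mkTrack(100 * (0:5), rep(0, 6))), 10.4)
  # stationary sphere
  expect_equal(trackVelocity(mkTrack(rep(3, 4), rep(-2, 4))), 0)
  # two-frame minimum works
  expect_equal(trackVelocity(mkTrack(c(0, 50), c(0, 0))), 5.2)
  expect_error(mkTrack(1, 1), "at least 2 frames")
})

test_that("velocity is invariant to rotation and temporal offset", {
  set.seed(31)
  x <- 70 * (0:9) + rnorm(10, 0, 0.5)
  y <- rnorm(10, 0, 0.5)
  v0 <- trackVelocity(mkTrack(x, y))
  for (th in c(0.4, 1.2, 2.9)) {
    xr <- cos(th) * x - sin(th) * y + 12
    yr <- sin(th) * x + cos(th) * y - 40
    expect_equal(trackVelocity(mkTrack(xr, yr)), v0, tolerance = 1e-9)
  }
  # shifting all frame indices by a constant changes nothing
  tk <- mkTrack(x, y)
  tk2 <- new("MicrosphereTrack", trackId = "t", veinId = "v",
             frameIndex = tk@frameIndex + 500L, xUm = x, yUm = y,
             frameRateHz = 104)
  expect_equal(trackVelocity(tk2), v0, tolerance = 1e-12)
})

test_that("vein velocity averages tracks and flags empty veins", {
  t6 <- mkTrack(6 / 104 * 1000 * (0:4), rep(0, 5))
  t7 <- mkTrack(7 / 104 * 1000 * (0:4), rep(0, 5))
  expect_equal(veinVelocity(list(t6, t7)), 6.5, tolerance = 1e-12)
  expect_equal(veinVelocity(list(t6)), 6, tolerance = 1e-12)
  expect_warning(v <- veinVelocity(list()), "returning NA")
  expect_true(is.na(v))
})

test_that("FWHM diameter: ideal boxcar geometry and degenerate profiles", {
  pr <- synthesizeCaliberProfile(30, blur_sd_um = 0, center_offset_um = 0)
  expect_equal(profileDiameter(pr), 30, tolerance = 1e-9)
  # flat profile has no peak
  flat <- new("CaliberProfile", vesselId = "f", positionUm = 0:20,
              intensity = rep(1, 21))
  expect_error(profileDiameter(flat), "no dominant peak")
})

test_that("FWHM is invariant to affine intensity scaling", {
  set.seed(12)
  pr <- synthesizeCaliberProfile(33, blur_sd_um = 2, noise_frac = 0)
  d0 <- profileDiameter(pr)
  for (sc in list(c(3, 0), c(0.25, 5), c(10, -2))) {
    pr2 <- new("CaliberProfile", vesselId = "s", positionUm = pr@positionUm,
               intensity = sc[1] * pr@intensity + sc[2])
    expect_equal(profileDiameter(pr2), d0, tolerance = 1e-9)
  }
})

test_that("lightly blurred boxcars stay within 1% of the true width", {
  for (d in c(25, 30, 36)) {
    pr <- synthesizeCaliberProfile(d, blur_sd_um = 2, noise_frac = 0,
                                   center_offset_um = 0.17)
    expect_lt(abs(profileDiameter(pr) - d) / d, 0.01)
  }
})
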