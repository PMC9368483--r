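test_that("lifetime follows from phase: tan(phi)/(2 pi f)", {
  # phase = arctan(1) at f = 1/(2 pi) Hz gives tau = 1 s
  expect_equal(estimateLifetime(phaseTrace(atan(1), 1 / (2 * pi))), 1)
  # least-squares phase fit inverts a noiseless sampled trace exactly
  tr <- synthesizePhaseTrace(30, constants = default_cst)
  tau_true <- tau0(default_cst) /
    (1 + default_cst@kqPerMmHgS * tau0(default_cst) * 30)
  expect_equal(estimateLifetime(tr), tau_true, tolerance = 1e-9)
})

test_that("non-physical phases are rejected", {
  # a phase at or beyond pi/2 cannot arise from a finite lifetime
  expect_error(phaseTrace(2, 1000), "0, pi/2")
  expect_error(phaseTrace(-0.1, 1000), "0, pi/2")
  # an empty trace with no phase carries no information
  expect_error(new("PhosphorescenceTrace", vesselId = "x",
                   modulationFrequencyHz = 1000, timeS = numeric(0),
                   signal = numeric(0), phaseRad = NA_real_),
               "samples or a precomputed phase")
})

test_that("noisy lifetime estimation is unbiased within Monte-Carlo CI", {
  set.seed(42)
  po2 <- 1.1289  # places tau near 500 us with the default constants
  taus <- replicate(500, estimateLifetime(
    synthesizePhaseTrace(po2, phase_noise_sd_rad = 0.01,
                         constants = default_cst)))
  tau_true <- tau0(default_cst) /
    (1 + default_cst@kqPerMmHgS * tau0(default_cst) * po2)
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - tau_true), 3 * se + 1e-12)
})

test_that("Stern-Volmer inversion: limits, midpoint, monotonicity", {
  t0 <- tau0(default_cst)
  expect_equal(lifetimeToPO2(t0, default_cst), 0)
  # tau = tau0/2 gives PO2 = 1/(kq * tau0) = 4.120364 mmHg at the defaults
  expect_equal(lifetimeToPO2(t0 / 2, default_cst),
               1 / (381 * 637e-6), tolerance = 1e-12)
  expect_equal(lifetimeToPO2(t0 / 2, default_cst), 4.120364,
               tolerance = 1e-6)
  # strictly decreasing in tau on (0, tau0]
  taus <- seq(t0 / 50, t0, length.out = 40)
  expect_true(all(diff(lifetimeToPO2(taus, default_cst)) < 0))
  # clamp window and error beyond it
  expect_equal(lifetimeToPO2(t0 * 1.01, default_cst), 0)
  expect_error(lifetimeToPO2(t0 * 1.05, default_cst), "unquenched")
  expect_error(lifetimeToPO2(-1e-6, default_cst), "positive")
})

test_that("Hill dissociation curve: midpoint, limits, independent oracle", {
  expect_equal(po2ToSO2(default_cst@p50MmHg, default_cst), 0.5)
  expect_equal(po2ToSO2(0, default_cst), 0)
  expect_gt(po2ToSO2(1e6, default_cst), 0.999999)
  expect_lt(po2ToSO2(1e6, default_cst), 1)
  # plain power-domain evaluation as the independent route
  oracle <- function(p, p50, n) p^n / (p50^n + p^n)
  for (p in c(5, 17, 30, 55, 120))
    expect_equal(po2ToSO2(p, default_cst), oracle(p, 40, 2.59),
                 tolerance = 1e-12)
  # monotone increasing
  grid <- seq(0, 200, by = 2.5)
  expect_true(all(diff(po2ToSO2(grid, default_cst)) > 0))
})

test_that("oxygen content sums bound and dissolved fractions", {
  expect_equal(oxygenContent(0, default_cst), 0)
  # dissolved term alone: 0.003 * 100 = 0.3 mLO2/dL
  hb_term <- default_cst@hbCapacityMlPerG * default_cst@hbGPerDl *
    po2ToSO2(100, default_cst)
  expect_equal(oxygenContent(100, default_cst) - hb_term, 0.3,
               tolerance = 1e-12)
  # exact decomposition everywhere
  for (p in c(1, 12, 33, 80)) {
    expect_equal(oxygenContent(p, default_cst) -
                   default_cst@solubilityMlPerDlPerMmHg * p,
                 default_cst@hbCapacityMlPerG * default_cst@hbGPerDl *
                   po2ToSO2(p, default_cst))
  }
  grid <- seq(0, 150, by = 1)
  expect_true(all(diff(oxygenContent(grid, default_cst)) > 0))
})

test_that("content inversion is the exact inverse and respects monotonicity", {
  expect_equal(contentToPO2(0, default_cst), 0)
  expect_equal(contentToPO2(oxygenContent(25, default_cst), default_cst),
               25, tolerance = 1e-6)
  # an arterial-level content (6.5 mLO2/dL) has a unique solution, above the
  # solution for a venous-level content (2.8)
  p_art <- contentToPO2(6.5, default_cst)
  p_ven <- contentToPO2(2.8, default_cst)
  expect_equal(oxygenContent(p_art, default_cst), 6.5, tolerance = 1e-6)
  expect_gt(p_art, p_ven)
  expect_error(contentToPO2(1e5, default_cst), "attainable maximum")
})

test_that("truth PO2 -> trace -> lifetime -> PO2 is the identity when noiseless", {
  for (p in c(0, 4, 19.5, 30, 60)) {
    tr <- synthesizePhaseTrace(p, constants = default_cst)
    expect_equal(lifetimeToPO2(estimateLifetime(tr), default_cst), p,
                 tolerance = 1e-6 * max(p, 1))
  }
})
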