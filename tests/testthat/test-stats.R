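test_that("pooled t-test matches the textbook formula and handles degeneracy", {
  tt <- twoSampleTTest(c(1, 2, 3), c(4, 5, 6))
  # by hand: means 2 and 5, pooled variance 1, t = -3 / sqrt(2/3)
  expect_equal(abs(tt$t), 3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(abs(tt$t), 3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  # identical groups
  same <- twoSampleTTest(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # zero variance
  expect_equal(twoSampleTTest(c(1, 1), c(1, 1))$p, 1)
  expect_error(twoSampleTTest(c(1, 1), c(2, 2)), "undefined")
  expect_error(twoSampleTTest(1, c(1, 2)), "at least 2")
})

test_that("t-test p-value agrees with a permutation reference", {
  a <- c(2.1, 3.4, 1.7, 4.2, 2.8, 3.0)
  b <- c(5.0, 4.1, 6.3, 5.7, 4.9, 4.4)
  tt <- twoSampleTTest(a, b)
  set.seed(17)
  pooled <- c(a, b)
  nperm <- 10000
  tstat <- function(g1, g2) {
    sp <- sqrt(((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
                 (length(g1) + length(g2) - 2))
    (mean(g1) - mean(g2)) / (sp * sqrt(1 / length(g1) + 1 / length(g2)))
  }
  perm <- replicate(nperm, {
    idx <- sample(12, 6)
    abs(tstat(pooled[idx], pooled[-idx]))
  })
  p_perm <- mean(perm >= abs(tt$t) - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / nperm) + 1 / nperm
  expect_lt(abs(tt$p - p_perm), 2 * se + 0.003)
})

test_that("Pearson correlation: exact cases and permutation reference", {
  x <- c(1, 2, 3, 5, 8, 9)
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_error(pearsonCorrelation(x, rep(2, 6)), "zero variance")
  expect_error(pearsonCorrelation(1:2, 2:3), "at least 3")

  set.seed(23)
  y <- x + rnorm(6, 0, 2)
  pc <- pearsonCorrelation(x, y)
  nperm <- 10000
  perm <- replicate(nperm, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= abs(pc$r) - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / nperm) + 1 / nperm
  expect_lt(abs(pc$p - p_perm), 2 * se + 0.01)
})

test_that("two-sample power: null case, monotonicity, reference agreement", {
  # zero effect gives exactly alpha (two-sided)
  expect_equal(powerTwoSampleT(5, 1, 13, 5, 1, 13, 0.05), 0.05,
               tolerance = 1e-9)
  # increasing effect and increasing n both increase power
  eff <- vapply(seq(0, 2, by = 0.25), function(d)
    powerTwoSampleT(d, 1, 10, 0, 1, 10), numeric(1))
  expect_true(all(diff(eff) > 0))
  ns <- vapply(c(4, 8, 16, 32, 64), function(n)
    powerTwoSampleT(1, 1, n, 0, 1, n), numeric(1))
  expect_true(all(diff(ns) > 0))
  # equal-n case agrees with the stock noncentral-t power routine up to the
  # opposite-tail mass, which power.t.test drops and this routine keeps
  for (d in c(0.5, 1, 1.6)) for (n in c(8, 13, 20)) {
    ref <- power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05)$power
    mine <- powerTwoSampleT(d, 1, n, 0, 1, n)
    expect_gte(mine + 1e-12, ref)
    expect_lt(mine - ref, 0.003)
  }
})

test_that("correlation power: null case, monotonicity, method agreement", {
  expect_equal(powerCorrelation(0, 26), 0.05, tolerance = 1e-9)
  expect_lt(abs(powerCorrelation(0, 19, method = "fisher") - 0.05), 0.002)
  rho_grid <- vapply(seq(0, 0.8, by = 0.1), powerCorrelation, numeric(1),
                     n = 20)
  expect_true(all(diff(rho_grid) > 0))
  n_grid <- vapply(c(6, 10, 19, 26, 50), function(n)
    powerCorrelation(0.5, n), numeric(1))
  expect_true(all(diff(n_grid) > 0))
  # the sampling density integrates to one
  expect_equal(integrate(retinox:::.dcorr, -1, 1, rho = 0.57, n = 26,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  # sign symmetry of the two-sided test
  expect_equal(powerCorrelation(0.5, 20), powerCorrelation(-0.5, 20),
               tolerance = 1e-8)
  # exact and Fisher-z routes agree to about a percentage point
  for (rho in c(0.3, 0.57)) for (n in c(19, 40)) {
    expect_lt(abs(powerCorrelation(rho, n) -
                    powerCorrelation(rho, n, method = "fisher")), 0.015)
  }
})

test_that("report assembles summaries, tests, correlations and powers", {
  coh <- generateCohort(tinyConfig(seed = 31), n_per_group = 6)
  rep <- suppressWarnings(buildReport(measureCohort(coh)))
  summ <- reportSummaries(rep)
  expect_setequal(unique(summ$group), c("WT", "5XFAD"))
  expect_true(all(c("v_v", "o2a", "trbf", "oef", "nfl_rgcl", "trt_oct",
                    "abeta42_brain") %in% summ$metric))
  tst <- reportTests(rep)
  expect_true(all(tst$p >= 0 & tst$p <= 1))
  corr <- reportCorrelations(rep)
  expect_true("o2a~v_v" %in% corr$pair)
  pw <- reportPowers(rep)
  expect_setequal(pw$label[pw$design == "two-sample-t"],
                  c("o2a", "o2v", "d_v", "v_v"))
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  expect_identical(rep@nTests, nrow(tst) + nrow(corr))
})

test_that("report of a single-group table contains summaries but no tests", {
  tt <- generateTruthTable(tinyConfig(seed = 32), n_per_group = 5)
  wt_only <- tt[tt$group == "WT", ]
  rep <- buildReport(wt_only)
  expect_gt(nrow(reportSummaries(rep)), 0)
  expect_equal(nrow(reportTests(rep)), 0)
  expect_equal(nrow(reportPowers(rep)[
    reportPowers(rep)$design == "two-sample-t", ]), 0)
})

test_that("report is deterministic given the input table", {
  tt <- generateTruthTable(tinyConfig(seed = 33), n_per_group = 5)
  r1 <- buildReport(tt); r2 <- buildReport(tt)
  expect_identical(reportSummaries(r1), reportSummaries(r2))
  expect_identical(reportPowers(r1), reportPowers(r2))
})
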