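test_that("vein flow follows the V * pi/4 * D^2 law with fixed unit factor", {
  # 10.5 mm/s through a 30 um vein: 10.5 * (pi/4) * 900 * 6e-5
  expect_equal(veinFlow(10.5, 30), 10.5 * pi / 4 * 900 * 6e-5,
               tolerance = 1e-12)
  expect_equal(veinFlow(0, 30), 0)
  # doubling the diameter quadruples the flow
  expect_equal(veinFlow(8, 60), 4 * veinFlow(8, 30), tolerance = 1e-12)
  expect_error(veinFlow(-1, 30), ">= 0")
  expect_error(veinFlow(1, 0), "> 0")
})

test_that("total flow is a permutation-invariant sum with an NA sentinel", {
  q <- veinFlow(c(10.5, 9, 11, 12), c(30, 28, 33, 29))
  expect_equal(totalFlow(q), sum(q))
  expect_equal(totalFlow(q[c(3, 1, 4, 2)]), totalFlow(q))
  expect_equal(totalFlow(q[1]), q[1])
  expect_warning(tf <- totalFlow(numeric(0)), "returning NA")
  expect_true(is.na(tf))
})

test_that("eye-level oxygen contents average vessels and difference them", {
  oc <- oxygenContents(6.5, 2.8)
  expect_equal(oc[["o2av"]], 3.7)
  expect_equal(oxygenContents(c(7.8, 7.8), c(4.3))[["o2av"]], 3.5)
  expect_equal(oxygenContents(5, 5)[["o2av"]], 0)
  expect_warning(oc2 <- oxygenContents(numeric(0), 2), "at least one")
  expect_true(all(is.na(oc2)))
  expect_warning(oxygenContents(2, 3), "negative arteriovenous")
})

test_that("delivery/metabolism metrics and the OEF identity", {
  dm <- deliveryMetabolism(1.73, 6.5, 3.7)
  expect_equal(dm[["do2"]], 112.45, tolerance = 1e-12)
  expect_equal(dm[["mo2"]], 64.01, tolerance = 1e-12)
  expect_equal(dm[["oef"]], 3.7 / 6.5, tolerance = 1e-12)
  # zero extraction
  dm0 <- deliveryMetabolism(1.73, 6.5, 0)
  expect_equal(dm0[["mo2"]], 0)
  expect_equal(dm0[["oef"]], 0)
  # scaling the flow leaves the extraction fraction unchanged
  for (c_ in c(0.5, 2, 7)) {
    dmc <- deliveryMetabolism(1.73 * c_, 6.5, 3.7)
    expect_equal(dmc[["do2"]], c_ * dm[["do2"]], tolerance = 1e-12)
    expect_equal(dmc[["oef"]], dm[["oef"]], tolerance = 1e-12)
  }
})

test_that("OEF reduces to o2av/o2a for arbitrary positive inputs", {
  set.seed(8)
  for (i in 1:25) {
    trbf <- runif(1, 0.5, 3); o2a <- runif(1, 3, 9)
    o2av <- runif(1, 0.1, o2a)
    dm <- deliveryMetabolism(trbf, o2a, o2av)
    expect_equal(dm[["oef"]], o2av / o2a, tolerance = 1e-12)
  }
})

test_that("two independent unit paths agree to machine precision", {
  # SI route: mm/s -> m/s, um -> m, m^3/s -> uL/min
  flow_si <- function(v, d) {
    q_m3_s <- (v * 1e-3) * (pi / 4) * (d * 1e-6)^2
    q_m3_s * 1e9 * 60
  }
  for (v in c(2, 6.6, 10.5)) for (d in c(22, 30, 36))
    expect_equal(veinFlow(v, d), flow_si(v, d), tolerance = 1e-12)
  # delivery: uL/min * mLO2/dL -> nLO2/min, vs litres throughout
  do2_si <- function(trbf, o2a) {
    (trbf * 1e-6) * (o2a * 1e-2) * 1e9   # L/min * LO2/Lblood -> nLO2/min
  }
  expect_equal(deliveryMetabolism(1.73, 6.5, 3.7)[["do2"]],
               do2_si(1.73, 6.5), tolerance = 1e-12)
})

test_that("per-animal-first aggregation differs from products of group means", {
  tt <- generateTruthTable(cohortConfig(seed = 13), n_per_group = 200)
  wt <- tt[tt$group == "WT", ]
  # group mean of per-animal DO2 is not TRBF-mean times O2A-mean
  expect_gt(abs(mean(wt$do2) - mean(wt$trbf) * mean(wt$o2a) * 10), 0.01)
  # and group mean OEF is not the ratio of group mean contents
  expect_gt(abs(mean(wt$oef) - mean(wt$o2av) / mean(wt$o2a)), 1e-4)
})
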