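test_that("measurement construction enforces its invariants", {
  expect_error(measurement(NaN), "invalid measurement")
  expect_error(measurement(Inf), "invalid measurement")
  expect_error(measurement(1, -0.1), "invalid measurement")
  m <- measurement(c(-8.23, -12.10), c(0.26, NA))
  expect_length(m, 2L)
  expect_true(is.na(m$uncertainty[2L]))
})

test_that("difference matches the benchmark-derived hopping columns", {
  # G2p hop TEMOA -> TEETOA from the two ABFEs
  d <- difference(measurement(-8.23, 0.26), measurement(-12.10, 0.26))
  expect_equal(d$value, 3.87, tolerance = 1e-12)
  expect_equal(d$uncertainty, sqrt(0.26^2 + 0.26^2), tolerance = 1e-12)
  expect_lt(abs(d$uncertainty - 0.37), 0.005)
  # G1 -> G4 on TEMOA from the two ABFEs
  d2 <- difference(measurement(-8.18, 0.32), measurement(-6.65, 0.32))
  expect_equal(d2$value, -1.53, tolerance = 1e-12)
  expect_equal(d2$uncertainty, sqrt(2) * 0.32, tolerance = 1e-12)
})

test_that("difference propagates absent uncertainty as absent", {
  d <- difference(measurement(1.0, 0.2), measurement(0.4))
  expect_equal(d$value, 0.6)
  expect_true(is.na(d$uncertainty))
})

test_that("difference is antisymmetric and zero on self-difference", {
  set.seed(42)
  for (i in 1:20) {
    a <- measurement(runif(1, -12, 0), runif(1, 0, 0.5))
    b <- measurement(runif(1, -12, 0), runif(1, 0, 0.5))
    expect_identical(difference(a, b)$value, -difference(b, a)$value)
    self <- difference(a, a)
    expect_identical(self$value, 0)
    expect_equal(self$uncertainty, sqrt(2) * a$uncertainty)
  }
})

test_that("swap free energy routes agree exactly on any 2x2 table", {
  set.seed(7)
  for (i in 1:50) {
    abfe <- matrix(runif(4, -12, 0), 2,
                   dimnames = list(c("A", "B"), c("L1", "L2")))
    # via BSFEs (hopping route)
    h1 <- rhfe_from_abfes(measurement(abfe["A", "L1"]),
                          measurement(abfe["B", "L1"]))
    h2 <- rhfe_from_abfes(measurement(abfe["A", "L2"]),
                          measurement(abfe["B", "L2"]))
    via_bsfe <- rsfe_from_bsfes(h1, h2)$value
    # via RBFEs
    rA <- difference(measurement(abfe["A", "L2"]), measurement(abfe["A", "L1"]))
    rB <- difference(measurement(abfe["B", "L2"]), measurement(abfe["B", "L1"]))
    via_rbfe <- rsfe_from_rbfes(rA, rB)$value
    # direct ABFE combination
    via_abfe <- (abfe["A", "L2"] + abfe["B", "L1"]) -
      (abfe["A", "L1"] + abfe["B", "L2"])
    expect_equal(via_bsfe, via_rbfe, tolerance = 1e-12)
    expect_equal(via_bsfe, via_abfe, tolerance = 1e-12)
  }
})

test_that("trypsin/thrombin swap from the two RBFEs", {
  # thrombin table row is Am -> Bz, so Bz -> Am is its negation
  d <- rsfe_from_rbfes(measurement(2.19, 0.32), measurement(-0.33, 0.32))
  expect_equal(d$value, 2.52, tolerance = 1e-12)
  expect_equal(d$uncertainty, sqrt(2) * 0.32, tolerance = 1e-12)
})

test_that("selectivity coefficient: closed forms and round trip", {
  ctx <- thermo_context()
  kT <- ctx$kB * ctx$temperature
  expect_equal(selectivity_coefficient(measurement(0))$coefficient, 1)
  expect_equal(selectivity_coefficient(measurement(-kT * log(10)))$coefficient,
               10, tolerance = 1e-12)
  s <- selectivity_coefficient(measurement(5.46), ctx)$coefficient
  expect_equal(s, exp(-5.46 / kT), tolerance = 1e-12)
  expect_equal(s, 1.06e-4, tolerance = 0.01)
  # round trip over 16 decades
  for (target in 10^seq(-8, 8, by = 2)) {
    back <- selectivity_coefficient(measurement(-kT * log(target)))$coefficient
    expect_equal(back, target, tolerance = 1e-12)
  }
})

test_that("selectivity ratio from a swap free energy", {
  expect_equal(selectivity_ratio_from_rsfe(measurement(0))$ratio, 1)
  r <- selectivity_ratio_from_rsfe(measurement(2.625))$ratio
  expect_equal(r, 81.7, tolerance = 0.002)
  r_rev <- selectivity_ratio_from_rsfe(measurement(-2.625))$ratio
  expect_equal(r_rev, 1 / r, tolerance = 1e-12)
})

test_that("ratio-of-coefficients identity holds for random hop pairs", {
  # with the coefficient oriented B-over-A and the swap ratio A-over-B,
  # ratio(h1 - h2) = coef(h2) / coef(h1)
  set.seed(11)
  for (i in 1:25) {
    h1 <- measurement(runif(1, -6, 6))
    h2 <- measurement(runif(1, -6, 6))
    lhs <- selectivity_ratio_from_rsfe(rsfe_from_bsfes(h1, h2))$ratio
    rhs <- selectivity_coefficient(h2)$coefficient /
      selectivity_coefficient(h1)$coefficient
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("pKi and binding-constant conversions", {
  expect_equal(dg_from_pki(0)$value, 0)
  kT300 <- 0.0019872041 * 300
  expect_equal(dg_from_pki(1)$value, -kT300 * log(10), tolerance = 1e-12)
  expect_equal(dg_from_pki(1)$value, -1.3725, tolerance = 5e-4)
  # experimental trypsin Bz-vs-Am relative affinity from pKi at 298.15 K
  ctx298 <- thermo_context(298.15)
  ddg <- difference(dg_from_pki(6.44, ctx298), dg_from_pki(7.51, ctx298))
  expect_equal(ddg$value, 1.46, tolerance = 0.005)

  expect_equal(dg_from_kb(1)$value, 0)
  expect_equal(kb_from_dg(measurement(-kT300)), exp(1), tolerance = 1e-12)
  expect_equal(dg_from_kb(1e6)$value, -8.236, tolerance = 5e-4)
  expect_error(dg_from_kb(0), "positive")
  expect_error(dg_from_kb(-1), "positive")
  for (kb in 10^seq(-6, 8, by = 2))
    expect_equal(kb_from_dg(dg_from_kb(kb)), kb, tolerance = 1e-12)
})
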