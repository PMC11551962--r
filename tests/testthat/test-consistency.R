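test_that("rmsd: hand values, permutation invariance, linear scaling", {
  expect_equal(fe_rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fe_rmsd(c(0, 0), c(1, -1)), 1.0)
  expect_error(fe_rmsd(numeric(0), numeric(0)), "empty")
  set.seed(5)
  a <- rnorm(10); b <- rnorm(10)
  p <- sample(10)
  expect_equal(fe_rmsd(a, b), fe_rmsd(a[p], b[p]), tolerance = 1e-12)
  expect_equal(fe_rmsd(3 * a, 3 * b), 3 * fe_rmsd(a, b), tolerance = 1e-12)
})

test_that("swap values recomputed from hopping data deviate by rmsd 0.31", {
  pairs <- sampl8_pair_table()
  rsfe <- fixtures("sampl8_rsfe")
  direct <- rsfe$value_kcal_mol
  from_rhfe <- vapply(seq_len(nrow(pairs)), function(k) {
    rsfe_from_bsfes(sampl8_rhfe_measurement(pairs$l1[k]),
                    sampl8_rhfe_measurement(pairs$l2[k]))$value
  }, 0)
  expect_equal(fe_rmsd(direct, from_rhfe), 0.31, tolerance = 0.01)
})

test_that("z test flags the discrepant direct-vs-indirect pair", {
  # TEETOA G1 -> G2p: direct RBFE vs difference of ABFEs
  rec <- compare_measurements(measurement(-6.19, 0.32),
                              measurement(-7.61, 0.42))
  expect_true(rec$significant)
  expect_equal(rec$delta, 1.42, tolerance = 1e-12)
  expect_equal(rec$combined_sigma, sqrt(0.16^2 + 0.21^2), tolerance = 1e-12)

  same <- compare_measurements(measurement(1.0, 0.3), measurement(1.0, 0.3))
  expect_equal(same$z, 0)
  expect_false(same$significant)
  expect_equal(same$p_value, 1)

  # the 1.96-sigma boundary sits at p = 0.05
  cs <- sqrt(2) * 0.1
  boundary <- compare_measurements(measurement(1.96 * cs, 0.2),
                                   measurement(0, 0.2))
  expect_equal(boundary$p_value, 0.05, tolerance = 1e-3)

  expect_error(compare_measurements(measurement(1), measurement(0, 0.2)),
               "cannot test")
})

test_that("comparisons are symmetric up to the sign of delta", {
  a <- measurement(1.3, 0.3); b <- measurement(0.9, 0.4)
  ab <- compare_measurements(a, b)
  ba <- compare_measurements(b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$z, ba$z)
})

test_that("forward/reverse hysteresis of the protein swap", {
  # values quoted in the narrative
  h <- hysteresis(measurement(2.05, 0.30), measurement(-2.32, 0.30))
  expect_equal(h$value, 0.27, tolerance = 1e-12)
  # tabulated forward/reverse pair
  tab <- fixtures("trypsin_thrombin_rsfe")
  h2 <- hysteresis(measurement(tab$value_kcal_mol[1L],
                               tab$uncertainty_2sigma[1L]),
                   measurement(tab$value_kcal_mol[2L],
                               tab$uncertainty_2sigma[2L]))
  expect_equal(h2$value, 0.51, tolerance = 1e-12)
  expect_equal(h2$uncertainty, sqrt(2) * 0.30, tolerance = 1e-12)
  # perfectly antisymmetric pair closes exactly
  expect_equal(hysteresis(measurement(1.5, 0.1),
                          measurement(-1.5, 0.1))$value, 0)
})

test_that("cycle closure: perturbed triangle and benchmark triangle", {
  tri <- fe_network("complex")
  tri <- add_rbfe(tri, "R", "a", "b", measurement(2, 0.2))
  tri <- add_rbfe(tri, "R", "b", "c", measurement(1, 0.2))
  tri <- add_rbfe(tri, "R", "a", "c", measurement(3, 0.2))
  cc <- cycle_closure(tri)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$closure, 0, tolerance = 1e-12)

  tri$edges$value[3L] <- 3 + 0.25  # perturb one edge by delta
  cc2 <- cycle_closure(tri)
  expect_equal(abs(cc2$closure), 0.25, tolerance = 1e-12)

  # TEMOA G1 -> G2p -> G3 -> G1 triangle from the measured RBFEs
  tm <- fe_network("complex")
  tm <- add_rbfe(tm, "TEMOA", "G1", "G2p", measurement(-5.08, 0.32))
  tm <- add_rbfe(tm, "TEMOA", "G2p", "G3", measurement(3.30, 0.32))
  tm <- add_rbfe(tm, "TEMOA", "G3", "G1", measurement(1.73, 0.30))
  cc3 <- cycle_closure(tm)
  expect_equal(cc3$closure, -0.05, tolerance = 1e-12)
  expect_equal(cc3$n_edges, 3L)

  # a forest has no cycles
  expect_equal(nrow(cycle_closure(fe_network("complex"))), 0L)
})

test_that("networks built from exact ground truth close every cycle", {
  truth <- generate_truth(2, 5, seed = 8)
  net <- sample_network(truth, edge_sigma = 0, seed = 1,
                        topology = "all_pairs", n_hop_edges = 3L)
  cc <- cycle_closure(net)
  expect_gt(nrow(cc), 0L)
  expect_true(all(abs(cc$closure) < 1e-12))
})

test_that("consistency_report aggregates records and rmsd", {
  direct <- measurement(c(1.0, 2.0), c(0.2, 0.2))
  indirect <- measurement(c(1.1, 1.7), c(0.2, 0.2))
  rep <- consistency_report(direct, indirect, labels = c("p1", "p2"))
  expect_equal(rep$n, 2L)
  expect_equal(rep$rmsd, sqrt(mean(c(0.1, 0.3)^2)), tolerance = 1e-12)
  expect_equal(nrow(rep$records), 2L)
})
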