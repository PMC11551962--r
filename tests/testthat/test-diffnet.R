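test_that("objective: hand-checked values and degenerate weights", {
  net <- fe_network("complex")
  net <- add_rbfe(net, "R", "a", "b", measurement(1.0, 0.4))
  expect_equal(fe_objective(net, c("R:a" = 0, "R:b" = 1.2)), 1.0)
  expect_equal(fe_objective(net, c("R:a" = 0, "R:b" = 1.0)), 0.0)
  expect_error(fe_objective(net, c("R:a" = 0)), "missing")
  z <- add_rbfe(net, "R", "b", "c", measurement(1.0, 0))
  expect_error(fe_objective(z, c("R:a" = 0, "R:b" = 1, "R:c" = 2)),
               "degenerate weight")

  # an assignment satisfying every edge of a consistent tree scores zero
  tree <- fe_network("complex")
  tree <- add_rbfe(tree, "R", "a", "b", measurement(2, 0.2))
  tree <- add_rbfe(tree, "R", "b", "c", measurement(-1, 0.2))
  expect_equal(fe_objective(tree, c("R:a" = 5, "R:b" = 7, "R:c" = 6)), 0)
})

test_that("two-node chain and simple anchored solves", {
  net <- fe_network("complex")
  net <- add_rbfe(net, "R", "a", "b", measurement(1.0, 0.2))
  net <- add_anchor(net, measurement(0), receptor = "R", ligand = "a")
  fit <- solve_network(net)
  expect_equal(unname(fit$estimates["R:b"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(fit$estimates["R:a"]), 0)
  expect_equal(fit$objective, 0, tolerance = 1e-12)
  # single-path uncertainty equals the edge's 2-sigma
  expect_equal(unname(fit$uncertainty_2sigma["R:b"]), 0.2, tolerance = 1e-12)
})

test_that("parallel replicate edges shrink the uncertainty by sqrt(2)", {
  net <- fe_network("complex")
  net <- add_rbfe(net, "R", "a", "b", measurement(1.0, 0.4))
  net <- add_rbfe(net, "R", "a", "b", measurement(1.2, 0.4))
  net <- add_anchor(net, measurement(0), receptor = "R", ligand = "a")
  fit <- solve_network(net)
  expect_equal(unname(fit$estimates["R:b"]), 1.1, tolerance = 1e-12)
  expect_equal(unname(fit$uncertainty_2sigma["R:b"]), 0.4 / sqrt(2),
               tolerance = 1e-12)
})

test_that("tree topologies are solved by exact path sums", {
  truth <- generate_truth(2, 6, seed = 4)
  net <- sample_network(truth, edge_sigma = 0.3, seed = 9,
                        topology = "chain", mode = "selectivity")
  fit <- solve_network(net)
  # expected: anchor + cumulative signed sums along the chain
  e <- net$edges
  expected <- net$anchors$value
  vals <- c("L1" = expected)
  for (k in seq_len(nrow(e)))  # chain edges appear in order L1-L2, L2-L3...
    vals[e$tail[k]] <- vals[e$head[k]] - e$value[k]
  expect_equal(fit$estimates[names(vals)], vals, tolerance = 1e-12)
  expect_equal(fit$objective, 0, tolerance = 1e-10)
})

test_that("anchor shift and variance scaling behave as gauge symmetries", {
  net <- random_selectivity_network(7, n_extra_edges = 5L, seed = 12)
  fit <- solve_network(net)
  # shifting the anchor shifts every estimate by the same constant
  shifted <- net
  shifted$anchors$value <- shifted$anchors$value + 3.25
  fit_s <- solve_network(shifted)
  expect_equal(fit_s$estimates, fit$estimates + 3.25, tolerance = 1e-10)
  # scaling all variances by k leaves estimates fixed, scales sigma by sqrt(k)
  scaled <- net
  scaled$edges$uncertainty <- scaled$edges$uncertainty * 2
  fit_k <- solve_network(scaled)
  expect_equal(fit_k$estimates, fit$estimates, tolerance = 1e-10)
  free <- setdiff(names(fit$estimates), net$anchors$node)
  expect_equal(fit_k$uncertainty_2sigma[free],
               2 * fit$uncertainty_2sigma[free], tolerance = 1e-10)
})

test_that("solve agrees with direct numerical minimization of the objective", {
  for (seed in 1:6) {
    n <- sample(3:6, 1)
    net <- random_selectivity_network(n, n_extra_edges = 2L, seed = seed)
    fit <- solve_network(net)
    ref <- oracle_solve(net)
    expect_equal(fit$estimates[names(ref)], ref, tolerance = 1e-6)
    expect_equal(fe_objective(net, fit$estimates), fit$objective,
                 tolerance = 1e-8)
  }
})

test_that("results are invariant to edge insertion order", {
  net <- random_selectivity_network(6, n_extra_edges = 4L, seed = 21)
  perm <- sample(nrow(net$edges))
  net2 <- net
  net2$edges <- net$edges[perm, ]
  rownames(net2$edges) <- NULL
  a <- solve_network(net)
  b <- solve_network(net2)
  expect_equal(a$estimates, b$estimates[names(a$estimates)],
               tolerance = 1e-10)
  expect_equal(a$objective, b$objective, tolerance = 1e-10)
})

test_that("unsolvable structures fail loudly, naming the component", {
  net <- fe_network("complex")
  net <- add_rbfe(net, "RA", "a", "b", measurement(1, 0.2))
  net <- add_rbfe(net, "RB", "a", "b", measurement(1, 0.2))
  net <- add_anchor(net, measurement(0), receptor = "RA", ligand = "a")
  expect_error(solve_network(net), "component without anchor")
  expect_error(solve_network(net), "RB:a")
})

test_that("residuals are consistent with the estimates", {
  fit <- solve_network(sampl8_network())
  x <- fit$estimates
  recomputed <- x[fit$residuals$head] - x[fit$residuals$tail] -
    fit$residuals$value
  expect_equal(unname(recomputed), fit$residuals$residual, tolerance = 1e-10)
})

test_that("soft anchoring fuses an uncertain reference", {
  net <- fe_network("complex")
  net <- add_rbfe(net, "R", "a", "b", measurement(1.0, 0.2))
  net <- add_anchor(net, measurement(0, 0.2), receptor = "R", ligand = "a")
  hard <- solve_network(net)
  soft <- solve_network(net, anchor_mode = "soft")
  # hard: the anchor is exact; soft: the anchor node gets a posterior sigma
  expect_equal(unname(hard$estimates["R:a"]), 0)
  expect_equal(unname(soft$estimates["R:a"]), 0, tolerance = 1e-10)
  expect_gt(unname(soft$uncertainty_2sigma["R:b"]),
            unname(hard$uncertainty_2sigma["R:b"]))
  # soft anchors without an uncertainty are rejected
  bad <- fe_network("complex")
  bad <- add_rbfe(bad, "R", "a", "b", measurement(1.0, 0.2))
  bad <- add_anchor(bad, measurement(0), receptor = "R", ligand = "a")
  expect_error(solve_network(bad, anchor_mode = "soft"), "soft")
})
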