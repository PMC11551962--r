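# Synthetic ground-truth affinity tables and Gaussian-noised networks.
# These emulate exactly the statistical structure the solver assumes --
# independent Gaussian errors on edge differences over a fixed
# receptor x ligand affinity table -- which makes them the right harness
# for parameter-recovery, unbiasedness and coverage experiments. They do
# not emulate force-field-level error correlation or convergence failure.

#' Generate a ground-truth affinity table
#'
#' Draws absolute binding free energies for every receptor-ligand pair
#' uniformly from `value_range`. All derived quantities (RBFE, RHFE/BSFE,
#' RSFE) are exact differences of this table, so every cycle closes to
#' machine precision by construction.
#'
#' @param n_receptors,n_ligands Positive counts.
#' @param value_range Length-2 numeric range of ABFE values (kcal/mol);
#'   default -12 to 0 spans typical host-guest affinities.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return An object of class `fe_truth`: list with `receptors`,
#'   `ligands` and the `abfe` matrix (receptors in rows).
#' @examples
#' truth <- generate_truth(2, 5, seed = 1)
#' truth$abfe
#' @export
generate_truth <- function(n_receptors = 2, n_ligands = 5,
                           value_range = c(-12, 0), seed = 1) {
  if (n_receptors < 1 || n_ligands < 1)
    stop("need at least one receptor and one ligand")
  if (length(value_range) != 2L || !all(is.finite(value_range)) ||
      value_range[1L] >= value_range[2L])
    stop("value_range must be a non-empty finite interval")
  set.seed(seed)
  receptors <- paste0("R", seq_len(n_receptors))
  ligands <- paste0("L", seq_len(n_ligands))
  abfe <- matrix(stats::runif(n_receptors * n_ligands,
                              value_range[1L], value_range[2L]),
                 nrow = n_receptors,
                 dimnames = list(receptors, ligands))
  structure(list(receptors = receptors, ligands = ligands, abfe = abfe),
            class = "fe_truth")
}

.check_truth <- function(truth) {
  if (!inherits(truth, "fe_truth")) stop("expected a 'fe_truth' object")
  invisible(truth)
}

.ligand_pairs <- function(ligands, topology) {
  n <- length(ligands)
  switch(topology,
    all_pairs = if (n < 2) NULL else {
      cb <- utils::combn(n, 2)
      data.frame(from = ligands[cb[1L, ]], to = ligands[cb[2L, ]],
                 stringsAsFactors = FALSE)
    },
    star = if (n < 2) NULL else
      data.frame(from = ligands[1L], to = ligands[-1L],
                 stringsAsFactors = FALSE),
    chain = if (n < 2) NULL else
      data.frame(from = ligands[-n], to = ligands[-1L],
                 stringsAsFactors = FALSE),
    stop("unknown topology: ", topology))
}

#' Exact derived edge tables of a ground truth
#'
#' `truth_rbfe()` tabulates all within-receptor ligand-pair differences,
#' `truth_rhfe()` the per-ligand hops between consecutive receptor pairs,
#' and `truth_rsfe()` the ligand-pair BSFE differences for one ordered
#' receptor pair. All values are exact differences of the ABFE table.
#'
#' @param truth A [generate_truth()] object.
#' @param receptor_from,receptor_to Ordered receptor pair for
#'   `truth_rsfe()`; defaults to the first two receptors.
#' @return A data frame in the same column layout as the edge-list format
#'   (see [read_edge_list()]), with exact values and zero uncertainty.
#' @export
truth_rbfe <- function(truth) {
  .check_truth(truth)
  out <- lapply(truth$receptors, function(r) {
    p <- .ligand_pairs(truth$ligands, "all_pairs")
    if (is.null(p)) return(NULL)
    data.frame(kind = "RBFE", receptor_a = r, ligand_a = p$from,
               receptor_b = r, ligand_b = p$to,
               value_kcal_mol = truth$abfe[r, p$to] - truth$abfe[r, p$from],
               uncertainty_2sigma = 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname truth_rbfe
#' @export
truth_rhfe <- function(truth) {
  .check_truth(truth)
  if (length(truth$receptors) < 2) stop("hopping needs two receptors")
  out <- lapply(seq_len(length(truth$receptors) - 1L), function(i) {
    ra <- truth$receptors[i]; rb <- truth$receptors[i + 1L]
    data.frame(kind = "RHFE", receptor_a = ra, ligand_a = truth$ligands,
               receptor_b = rb, ligand_b = truth$ligands,
               value_kcal_mol = truth$abfe[rb, ] - truth$abfe[ra, ],
               uncertainty_2sigma = 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname truth_rbfe
#' @export
truth_rsfe <- function(truth, receptor_from = NULL, receptor_to = NULL) {
  .check_truth(truth)
  if (length(truth$receptors) < 2) stop("swapping needs two receptors")
  if (is.null(receptor_from)) receptor_from <- truth$receptors[1L]
  if (is.null(receptor_to)) receptor_to <- truth$receptors[2L]
  bsfe <- truth$abfe[receptor_to, ] - truth$abfe[receptor_from, ]
  p <- .ligand_pairs(truth$ligands, "all_pairs")
  if (is.null(p)) stop("swapping needs two ligands")
  data.frame(kind = "RSFE", receptor_a = receptor_from, ligand_a = p$from,
             receptor_b = receptor_to, ligand_b = p$to,
             value_kcal_mol = unname(bsfe[p$from] - bsfe[p$to]),
             uncertainty_2sigma = 0, stringsAsFactors = FALSE)
}

#' Sample a Gaussian-noised network from a ground truth
#'
#' Builds a measurement network whose edge values are the exact
#' ground-truth differences plus independent `N(0, edge_sigma^2)` noise,
#' with each edge's uncertainty recorded as `2 * edge_sigma` (the
#' reporting convention). One anchor is placed at the exact true value of
#' the first node (first receptor-ligand complex, or first ligand in
#' selectivity mode), so noiseless networks are recovered exactly.
#'
#' In complex mode, each receptor contributes a ligand-pair RBFE
#' subnetwork with the requested `topology`, and the first `n_hop_edges`
#' ligands contribute RHFE edges between consecutive receptors, tying the
#' subnetworks together. In selectivity mode the ligand nodes are joined
#' directly by RSFE edges with the requested topology.
#'
#' @param truth A [generate_truth()] object.
#' @param edge_sigma 1-sigma of the added Gaussian noise (kcal/mol),
#'   `>= 0`.
#' @param seed Integer seed; fixed seed gives an identical network.
#' @param topology `"all_pairs"` (default), `"star"` or `"chain"`.
#' @param n_hop_edges Number of ligands given hopping edges (complex
#'   mode), between 1 and the number of ligands.
#' @param mode `"complex"` or `"selectivity"`.
#' @return A [fe_network()] ready for [solve_network()].
#' @examples
#' truth <- generate_truth(2, 5, seed = 1)
#' net <- sample_network(truth, edge_sigma = 0.15, seed = 7)
#' solve_network(net)
#' @export
sample_network <- function(truth, edge_sigma, seed,
                           topology = c("all_pairs", "star", "chain"),
                           n_hop_edges = 1L,
                           mode = c("complex", "selectivity")) {
  .check_truth(truth)
  topology <- match.arg(topology)
  mode <- match.arg(mode)
  if (!is.numeric(edge_sigma) || edge_sigma < 0)
    stop("edge_sigma must be >= 0")
  set.seed(seed)
  noise <- function(n) stats::rnorm(n, 0, edge_sigma)
  u <- 2 * edge_sigma
  if (mode == "complex") {
    net <- fe_network("complex")
    pairs <- .ligand_pairs(truth$ligands, topology)
    for (r in truth$receptors) {
      if (!is.null(pairs)) {
        d <- truth$abfe[r, pairs$to] - truth$abfe[r, pairs$from] +
          noise(nrow(pairs))
        for (k in seq_len(nrow(pairs)))
          net <- add_rbfe(net, r, pairs$from[k], pairs$to[k],
                          measurement(d[k], u))
      }
    }
    if (length(truth$receptors) > 1L) {
      n_hop_edges <- max(1L, min(as.integer(n_hop_edges),
                                 length(truth$ligands)))
      hop_lig <- truth$ligands[seq_len(n_hop_edges)]
      for (i in seq_len(length(truth$receptors) - 1L)) {
        ra <- truth$receptors[i]; rb <- truth$receptors[i + 1L]
        d <- truth$abfe[rb, hop_lig] - truth$abfe[ra, hop_lig] +
          noise(length(hop_lig))
        for (k in seq_along(hop_lig))
          net <- add_rhfe(net, hop_lig[k], ra, rb, measurement(d[k], u))
      }
    }
    net <- add_anchor(net,
                      measurement(truth$abfe[1L, 1L]),
                      receptor = truth$receptors[1L],
                      ligand = truth$ligands[1L])
  } else {
    if (length(truth$receptors) < 2) stop("selectivity mode needs two receptors")
    ra <- truth$receptors[1L]; rb <- truth$receptors[2L]
    bsfe <- truth$abfe[rb, ] - truth$abfe[ra, ]
    net <- fe_network("selectivity", receptors = c(ra, rb))
    pairs <- .ligand_pairs(truth$ligands, topology)
    if (is.null(pairs)) stop("selectivity mode needs two ligands")
    d <- unname(bsfe[pairs$from] - bsfe[pairs$to]) + noise(nrow(pairs))
    for (k in seq_len(nrow(pairs)))
      net <- add_rsfe(net, pairs$from[k], pairs$to[k], measurement(d[k], u))
    net <- add_anchor(net, measurement(unname(bsfe[1L])),
                      ligand = truth$ligands[1L])
  }
  net
}

#' True node values of a ground truth, aligned with network nodes
#'
#' @param truth A [generate_truth()] object.
#' @param mode `"complex"` (ABFE per complex node) or `"selectivity"`
#'   (BSFE per ligand for the first ordered receptor pair).
#' @return Named numeric vector keyed by node id.
#' @export
truth_node_values <- function(truth, mode = c("complex", "selectivity")) {
  .check_truth(truth)
  mode <- match.arg(mode)
  if (mode == "complex") {
    grid <- expand.grid(receptor = truth$receptors, ligand = truth$ligands,
                        stringsAsFactors = FALSE)
    stats::setNames(truth$abfe[cbind(grid$receptor, grid$ligand)],
                    complex_node_id(grid$receptor, grid$ligand))
  } else {
    if (length(truth$receptors) < 2) stop("selectivity mode needs two receptors")
    stats::setNames(truth$abfe[2L, ] - truth$abfe[1L, ], truth$ligands)
  }
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeatedly samples a noised network from the same ground truth, solves
#' it, and aggregates the estimation error against the true node values:
#' per-node bias and RMSE, overall bias and RMSE, and the empirical
#' coverage of the reported 2-sigma intervals. Anchored nodes are excluded
#' from the aggregates (their error is identically zero under hard
#' anchoring).
#'
#' @param truth A [generate_truth()] object.
#' @param edge_sigma 1-sigma Gaussian edge noise (kcal/mol).
#' @param n_replicates Number of independent replicates (`>= 1`).
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @inheritParams sample_network
#' @return A list with `per_node` (data frame: node, truth, bias, rmse,
#'   coverage), `bias`, `rmse`, `coverage` (overall), `n_replicates`,
#'   `edge_sigma`.
#' @examples
#' truth <- generate_truth(2, 4, seed = 1)
#' recovery_experiment(truth, edge_sigma = 0.2, n_replicates = 20, seed = 5)
#' @export
recovery_experiment <- function(truth, edge_sigma, n_replicates,
                                topology = "all_pairs", n_hop_edges = 1L,
                                mode = "complex", seed = 1) {
  .check_truth(truth)
  if (n_replicates < 1) stop("need at least one replicate")
  true_vals <- truth_node_values(truth, mode)
  err <- cov <- NULL
  for (i in seq_len(n_replicates)) {
    net <- sample_network(truth, edge_sigma, seed = seed + i - 1L,
                          topology = topology, n_hop_edges = n_hop_edges,
                          mode = mode)
    fit <- solve_network(net)
    free <- setdiff(names(fit$estimates), fit$anchors$node)
    e_i <- fit$estimates[free] - true_vals[free]
    c_i <- abs(e_i) <= fit$uncertainty_2sigma[free]
    err <- rbind(err, e_i)
    cov <- rbind(cov, c_i)
  }
  per_node <- data.frame(node = colnames(err),
                         truth = unname(true_vals[colnames(err)]),
                         bias = unname(colMeans(err)),
                         rmse = unname(sqrt(colMeans(err^2))),
                         coverage = unname(colMeans(cov)),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(per_node = per_node,
       bias = mean(err), rmse = sqrt(mean(err^2)), coverage = mean(cov),
       n_replicates = n_replicates, edge_sigma = edge_sigma)
}
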