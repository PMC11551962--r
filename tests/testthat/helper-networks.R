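# Shared helpers: random connected networks and an independent
# brute-force oracle for the weighted least-squares solve.

# Random connected selectivity-mode network: a random spanning tree plus
# extra chords, random edge values and uncertainties, anchored at node 1.
random_selectivity_network <- function(n_nodes, n_extra_edges = 2L,
                                       seed = 1) {
  set.seed(seed)
  ligands <- paste0("L", seq_len(n_nodes))
  net <- fe_network("selectivity", receptors = c("A", "B"))
  add_edge <- function(net, i, j) {
    add_rsfe(net, ligands[i], ligands[j],
             measurement(stats::runif(1, -5, 5),
                         stats::runif(1, 0.1, 0.6)))
  }
  for (i in seq_len(n_nodes - 1L))
    net <- add_edge(net, i + 1L, sample.int(i, 1L))
  for (k in seq_len(n_extra_edges)) {
    repeat {
      ij <- sample.int(n_nodes, 2L)
      if (ij[1L] != ij[2L]) break
    }
    net <- add_edge(net, ij[1L], ij[2L])
  }
  add_anchor(net, measurement(stats::runif(1, -3, 3)), ligand = ligands[1L])
}

# Independent oracle: direct numerical minimization of the objective over
# the free nodes, never touching the linear-algebra path.
oracle_solve <- function(network) {
  nodes <- network_nodes(network)
  anchored <- network$anchors$node
  free <- setdiff(nodes, anchored)
  anchor_vals <- stats::setNames(network$anchors$value, anchored)
  fn <- function(par) {
    x <- c(stats::setNames(par, free), anchor_vals)
    fe_objective(network, x)
  }
  start <- rep(mean(network$anchors$value), length(free))
  opt <- stats::optim(start, fn, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  c(stats::setNames(opt$par, free), anchor_vals)
}

# Measurement vectors from the packaged tables, keyed by guest pair
sampl8_pair_table <- function() {
  data.frame(l1 = c("G1", "G1", "G1", "G1", "G2p", "G2p", "G2p",
                    "G3", "G3", "G4"),
             l2 = c("G2p", "G3", "G4", "G5", "G3", "G4", "G5",
                    "G4", "G5", "G5"),
             stringsAsFactors = FALSE)
}

sampl8_rhfe_measurement <- function(guest) {
  tab <- fixtures("sampl8_rhfe")
  row <- tab[tab$ligand_a == guest, ]
  measurement(row$value_kcal_mol, row$uncertainty_2sigma)
}
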