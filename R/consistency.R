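# Cross-validation diagnostics for free-energy data: the same physical
# quantity is usually reachable along several computational routes (a
# direct calculation versus a combination of others), and systematic
# disagreement between routes flags convergence or setup problems.

#' Root-mean-square deviation between two sets of values
#'
#' @param a,b Numeric vectors of equal length (kcal/mol), paired.
#' @return `sqrt(mean((a - b)^2))`.
#' @examples
#' fe_rmsd(c(0, 0), c(1, -1))
#' @export
fe_rmsd <- function(a, b) {
  if (length(a) == 0L) stop("rmsd of an empty list is undefined")
  if (length(a) != length(b)) stop("rmsd needs paired vectors")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("rmsd needs finite values")
  sqrt(mean((a - b)^2))
}

#' Significance test of a direct-versus-indirect discrepancy
#'
#' Compares two independent estimates of the same free energy (for
#' example, a directly calculated RBFE against the difference of two
#' ABFEs). The discrepancy `delta = direct - indirect` is referred to its
#' combined standard deviation and tested with a two-sided z test, the
#' large-sample limit of the t test; under the Gaussian error model of
#' the measurements this is the natural reference distribution.
#'
#' Both inputs carry 2-sigma uncertainties, so the combined 1-sigma is
#' `sqrt((u_direct/2)^2 + (u_indirect/2)^2)`. Covariance between routes
#' that share inputs is ignored, as in the usual quadrature columns of
#' free-energy tables; this overstates the combined sigma slightly when
#' the routes overlap.
#'
#' @param direct,indirect [measurement()]s with uncertainties present.
#' @param alpha Two-sided significance level (default 0.05).
#' @param label Optional label carried into the record.
#' @return A one-row data frame of class `fe_comparison`: `label`,
#'   `direct`, `indirect`, `delta`, `combined_sigma` (1-sigma), `z`,
#'   `p_value`, `significant`.
#' @examples
#' compare_measurements(measurement(-6.19, 0.32), measurement(-7.61, 0.42))
#' @export
compare_measurements <- function(direct, indirect, alpha = 0.05,
                                 label = "") {
  direct <- .as_measurement(direct, "direct")
  indirect <- .as_measurement(indirect, "indirect")
  if (any(is.na(direct$uncertainty)) || any(is.na(indirect$uncertainty)))
    stop("cannot test: both measurements need an uncertainty")
  if (any(direct$uncertainty == 0 & indirect$uncertainty == 0))
    stop("cannot test: at least one uncertainty must be positive")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  delta <- direct$value - indirect$value
  combined_sigma <- sqrt((direct$uncertainty / 2)^2 +
                         (indirect$uncertainty / 2)^2)
  z <- abs(delta) / combined_sigma
  p <- 2 * stats::pnorm(-z)
  structure(data.frame(label = rep_len(label, length(delta)),
                       direct = direct$value, indirect = indirect$value,
                       delta = delta, combined_sigma = combined_sigma,
                       z = z, p_value = p, significant = p < alpha,
                       stringsAsFactors = FALSE),
            class = c("fe_comparison", "data.frame"), alpha = alpha)
}

#' Consistency report over paired direct/indirect estimates
#'
#' Runs [compare_measurements()] element-wise over two measurement vectors
#' and aggregates the discrepancies into an RMSD.
#'
#' @param direct,indirect [measurement()] vectors of equal length.
#' @param labels Optional character labels per pair.
#' @param alpha Two-sided significance level.
#' @return A list with `records` (the `fe_comparison` data frame), `rmsd`
#'   and `n`.
#' @export
consistency_report <- function(direct, indirect, labels = NULL,
                               alpha = 0.05) {
  direct <- .as_measurement(direct, "direct")
  indirect <- .as_measurement(indirect, "indirect")
  if (length(direct) != length(indirect))
    stop("direct and indirect must pair up")
  if (is.null(labels)) labels <- as.character(seq_along(direct$value))
  records <- compare_measurements(direct, indirect, alpha = alpha,
                                  label = labels)
  list(records = records,
       rmsd = fe_rmsd(direct$value, indirect$value),
       n = length(direct$value))
}

#' Forward/reverse hysteresis of a swap calculation
#'
#' A transformation computed forward and then in reverse traverses a
#' closed cycle, so the two estimates must sum to zero for converged,
#' consistent data. The hysteresis is `|forward + reverse|` with
#' quadrature uncertainty; values within the combined uncertainty indicate
#' a reliable calculation.
#'
#' @param forward,reverse [measurement()]s of the same transformation in
#'   opposite directions.
#' @return A `fe_measurement` holding the deviation.
#' @examples
#' hysteresis(measurement(2.05, 0.30), measurement(-2.32, 0.30))
#' @export
hysteresis <- function(forward, reverse) {
  forward <- .as_measurement(forward, "forward")
  reverse <- .as_measurement(reverse, "reverse")
  measurement(abs(forward$value + reverse$value),
              sqrt(forward$uncertainty^2 + reverse$uncertainty^2))
}

#' Cycle-closure analysis of a free-energy network
#'
#' Free energy is a state function, so the signed sum of edge values
#' around any closed cycle of a thermodynamically consistent network is
#' zero within statistical uncertainty. This computes the closure of each
#' independent (fundamental) cycle: a spanning forest is built and every
#' chord edge defines one cycle through the tree path between its
#' endpoints. Edge values are added when traversed tail-to-head and
#' subtracted otherwise; the closure uncertainty is the quadrature of the
#' member edges' 2-sigma values.
#'
#' @param network A [fe_network()].
#' @return A data frame with one row per independent cycle: `cycle` (the
#'   node sequence), `n_edges`, `closure` (kcal/mol) and
#'   `uncertainty_2sigma` (`NA` if any member edge lacks one). Zero rows
#'   when the network is a forest.
#' @examples
#' net <- fe_network("complex")
#' net <- add_rbfe(net, "R", "a", "b", measurement(-5.08, 0.32))
#' net <- add_rbfe(net, "R", "b", "c", measurement(3.30, 0.32))
#' net <- add_rbfe(net, "R", "c", "a", measurement(1.73, 0.30))
#' cycle_closure(net)
#' @export
cycle_closure <- function(network) {
  .check_network(network)
  e <- network$edges
  empty <- data.frame(cycle = character(), n_edges = integer(),
                      closure = numeric(), uncertainty_2sigma = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(e) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$tail, to = e$head, edge_index = seq_len(nrow(e))),
    directed = FALSE)
  # spanning forest: edges that connect previously separate components
  comp <- stats::setNames(seq_along(igraph::V(g)),
                          igraph::V(g)$name)
  find <- function(i) { while (comp[[i]] != i) i <- comp[[i]]; i }
  in_tree <- logical(nrow(e))
  for (k in seq_len(nrow(e))) {
    i <- find(match(e$tail[k], names(comp)))
    j <- find(match(e$head[k], names(comp)))
    if (i != j) { comp[j] <- i; in_tree[k] <- TRUE }
  }
  if (all(in_tree)) return(empty)
  tree <- igraph::subgraph_from_edges(g, which(in_tree),
                                      delete.vertices = FALSE)
  out <- lapply(which(!in_tree), function(k) {
    p <- igraph::shortest_paths(tree, from = e$head[k], to = e$tail[k],
                                output = "both")
    vpath <- names(unlist(p$vpath[[1]]))
    epath <- p$epath[[1]]
    tree_idx <- igraph::edge_attr(tree, "edge_index", epath)
    total <- e$value[k]
    usq <- e$uncertainty[k]^2
    # walk the tree path head(k) -> ... -> tail(k), signing each edge
    for (s in seq_along(tree_idx)) {
      ek <- tree_idx[s]
      from_node <- vpath[s]
      sign_k <- if (e$tail[ek] == from_node) 1 else -1
      total <- total + sign_k * e$value[ek]
      usq <- usq + e$uncertainty[ek]^2
    }
    data.frame(cycle = paste(c(e$tail[k], vpath), collapse = " -> "),
               n_edges = length(tree_idx) + 1L,
               closure = total,
               uncertainty_2sigma = sqrt(usq),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
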