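# Generalized DiffNet: maximum-likelihood estimation of node free energies
# from a network of measured pairwise differences. Under independent
# Gaussian edge errors the negative log-likelihood is the variance-weighted
# least-squares objective
#     sum_e (x_head - x_tail - d_e)^2 / sigma_e^2 ,
# whose normal equations form a weighted graph Laplacian. Anchored nodes
# are eliminated from the system (hard mode) or restrained by a prior term
# (soft mode). The same machinery serves complex-mode networks (node values
# are ABFEs, edges are RBFEs/RHFEs) and selectivity-mode networks (node
# values are BSFEs, edges are RSFEs).

.edge_sigma <- function(network) {
  u <- network$edges$uncertainty
  if (any(is.na(u)))
    stop("edges ", paste(which(is.na(u)), collapse = ", "),
         " have no uncertainty; the solver needs an error bar per edge")
  sigma <- u / 2
  if (all(sigma == 0) && length(sigma) > 0L) {
    # exact (noiseless) data: weights are arbitrary, use unit sigma
    sigma <- rep(1, length(sigma))
  } else if (any(sigma == 0)) {
    stop("degenerate weight: edges ", paste(which(u == 0), collapse = ", "),
         " report zero uncertainty; model exact constraints as anchors")
  }
  sigma
}

#' DiffNet weighted least-squares objective
#'
#' Evaluates the variance-weighted sum of squared edge residuals,
#' `sum((x_head - x_tail - d_e)^2 / sigma_e^2)` with
#' `sigma_e = uncertainty_e / 2`, for a candidate assignment of node
#' values. Anchored nodes contribute no term of their own under the
#' default hard-anchor convention; with `anchor_mode = "soft"` each anchor
#' adds a prior term `(x_a - value_a)^2 / (uncertainty_a / 2)^2`.
#'
#' @param network A validated [fe_network()].
#' @param assignment Named numeric vector covering every node.
#' @param anchor_mode `"hard"` (default) or `"soft"`.
#' @return The dimensionless objective value.
#' @examples
#' net <- fe_network("complex")
#' net <- add_rbfe(net, "R", "a", "b", measurement(1.0, 0.4))
#' fe_objective(net, c("R:a" = 0, "R:b" = 1.2))  # (0.2/0.2)^2 = 1
#' @export
fe_objective <- function(network, assignment,
                         anchor_mode = c("hard", "soft")) {
  .check_network(network)
  anchor_mode <- match.arg(anchor_mode)
  nodes <- network_nodes(network)
  if (!all(nodes %in% names(assignment)))
    stop("assignment must cover all nodes; missing: ",
         paste(setdiff(nodes, names(assignment)), collapse = ", "))
  u <- network$edges$uncertainty
  if (any(is.na(u) | u == 0))
    stop("degenerate weight: every edge needs a positive uncertainty")
  x <- assignment
  r <- x[network$edges$head] - x[network$edges$tail] - network$edges$value
  obj <- sum((r / (u / 2))^2)
  if (anchor_mode == "soft" && nrow(network$anchors) > 0L) {
    ua <- network$anchors$uncertainty
    if (any(is.na(ua) | ua == 0))
      stop("soft anchors need a positive uncertainty")
    ra <- x[network$anchors$node] - network$anchors$value
    obj <- obj + sum((ra / (ua / 2))^2)
  }
  unname(obj)
}

#' Solve a free-energy network by generalized DiffNet
#'
#' Finds the node free energies most consistent with the measured edge
#' differences: the unique minimizer of [fe_objective()]. The normal
#' equations are the reduced weighted-Laplacian system, solved by a
#' symmetric positive-definite (Cholesky) factorization; there is no
#' randomness and no pseudo-inverse fallback, so a structurally
#' under-determined network fails loudly rather than returning a silently
#' gauge-fixed answer.
#'
#' With hard anchors (default), anchored nodes are fixed exactly at their
#' reference values and eliminated from the linear system — the convention
#' used when a single reference complex sets the scale. With
#' `anchor_mode = "soft"`, anchors enter as Gaussian prior terms weighted
#' by their own uncertainties, which fuses several uncertain references
#' instead of trusting one exactly.
#'
#' Per-node uncertainties are reported as 2-sigma, with `sigma_i^2` the
#' i-th diagonal element of the inverse reduced precision matrix (edge
#' weights `1/sigma_e^2`). Hard-anchored nodes report their anchor's
#' uncertainty (0 if absent).
#'
#' @param network A [fe_network()] that passes [validate_network()].
#' @param anchor_mode `"hard"` (default) or `"soft"`.
#' @return An object of class `diffnet_fit`: list with `estimates` and
#'   `uncertainty_2sigma` (named numeric vectors), `residuals` (data frame
#'   with per-edge fitted differences and residuals), `objective`,
#'   `condition_number`, `mode`, `anchor_mode`, and the input `anchors`.
#' @examples
#' net <- fe_network("complex")
#' net <- add_rbfe(net, "R", "a", "b", measurement(1.0, 0.2))
#' net <- add_anchor(net, measurement(0), receptor = "R", ligand = "a")
#' solve_network(net)
#' @export
solve_network <- function(network, anchor_mode = c("hard", "soft")) {
  .check_network(network)
  anchor_mode <- match.arg(anchor_mode)
  findings <- validate_network(network)
  if (length(findings) > 0L)
    stop("network is not solvable:\n  ", paste(findings, collapse = "\n  "))
  nodes <- sort(network_nodes(network))
  if (length(nodes) == 0L) stop("empty network")
  e <- network$edges
  sigma <- .edge_sigma(network)
  w <- 1 / sigma^2

  anchors <- network$anchors
  anchors <- anchors[!duplicated(anchors$node), , drop = FALSE]
  anchor_value <- stats::setNames(anchors$value, anchors$node)

  if (anchor_mode == "hard") {
    free <- setdiff(nodes, anchors$node)
  } else {
    free <- nodes
    ua <- anchors$uncertainty
    if (any(is.na(ua) | ua == 0))
      stop("soft anchoring needs a positive uncertainty on every anchor")
  }

  x <- stats::setNames(numeric(length(nodes)), nodes)
  cond <- 1
  if (length(free) > 0L) {
    n <- length(free)
    A <- matrix(0, n, n, dimnames = list(free, free))
    b <- stats::setNames(numeric(n), free)
    ti <- match(e$tail, free)
    hi <- match(e$head, free)
    for (k in seq_len(nrow(e))) {
      i <- ti[k]; j <- hi[k]; wk <- w[k]; d <- e$value[k]
      if (!is.na(i) && !is.na(j)) {
        A[i, i] <- A[i, i] + wk; A[j, j] <- A[j, j] + wk
        A[i, j] <- A[i, j] - wk; A[j, i] <- A[j, i] - wk
        b[j] <- b[j] + wk * d;   b[i] <- b[i] - wk * d
      } else if (is.na(i) && !is.na(j)) {
        A[j, j] <- A[j, j] + wk
        b[j] <- b[j] + wk * (anchor_value[e$tail[k]] + d)
      } else if (!is.na(i) && is.na(j)) {
        A[i, i] <- A[i, i] + wk
        b[i] <- b[i] + wk * (anchor_value[e$head[k]] - d)
      }
    }
    if (anchor_mode == "soft") {
      for (k in seq_len(nrow(anchors))) {
        i <- match(anchors$node[k], free)
        wa <- 1 / (anchors$uncertainty[k] / 2)^2
        A[i, i] <- A[i, i] + wa
        b[i] <- b[i] + wa * anchors$value[k]
      }
    }
    R <- tryCatch(chol(A), error = function(err)
      stop("singular reduced system: a component lacks the constraints ",
           "needed to determine it (", conditionMessage(err), ")"))
    cond <- kappa(A, exact = FALSE)
    if (cond > 1e12)
      warning("ill-conditioned network: condition number ",
              format(cond, digits = 3))
    prec_inv <- chol2inv(R)
    x[free] <- drop(prec_inv %*% b)
    node_sigma <- stats::setNames(sqrt(diag(prec_inv)), free)
  } else {
    node_sigma <- stats::setNames(numeric(0), character(0))
  }

  unc <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  unc[names(node_sigma)] <- 2 * node_sigma
  if (anchor_mode == "hard") {
    x[anchors$node] <- anchors$value
    au <- ifelse(is.na(anchors$uncertainty), 0, anchors$uncertainty)
    unc[anchors$node] <- au
  }

  fitted <- x[e$head] - x[e$tail]
  residuals <- data.frame(kind = e$kind, tail = e$tail, head = e$head,
                          value = e$value, uncertainty = e$uncertainty,
                          fitted = unname(fitted),
                          residual = unname(fitted - e$value),
                          stringsAsFactors = FALSE)
  objective <- sum((residuals$residual / sigma)^2)
  if (anchor_mode == "soft" && nrow(anchors) > 0L)
    objective <- objective +
      sum(((x[anchors$node] - anchors$value) / (anchors$uncertainty / 2))^2)

  structure(list(mode = network$mode, anchor_mode = anchor_mode,
                 estimates = x, uncertainty_2sigma = unc,
                 residuals = residuals, objective = unname(objective),
                 condition_number = cond, anchors = anchors,
                 receptors = network$receptors),
            class = "diffnet_fit")
}

#' Solve a selectivity (BSFE) network
#'
#' Convenience wrapper around [solve_network()] that insists on
#' selectivity mode: node estimates are binding selectivity free energies
#' of each ligand for the network's ordered receptor pair, inferred from
#' receptor-swapping edges and one (or more) reference BSFE anchors.
#'
#' @inheritParams solve_network
#' @return A `diffnet_fit`; see [solve_network()].
#' @export
solve_selectivity <- function(network, anchor_mode = c("hard", "soft")) {
  .check_network(network)
  if (network$mode != "selectivity")
    stop("solve_selectivity() expects a selectivity-mode network")
  solve_network(network, anchor_mode = anchor_mode)
}

#' Per-node uncertainties of a solved network
#'
#' @param fit A `diffnet_fit` from [solve_network()].
#' @return Named numeric vector of 2-sigma uncertainties, one per node.
#' @export
node_uncertainties <- function(fit) {
  if (!inherits(fit, "diffnet_fit")) stop("expected a 'diffnet_fit'")
  fit$uncertainty_2sigma
}

#' @export
print.diffnet_fit <- function(x, ...) {
  cat(sprintf("DiffNet fit (%s mode, %s anchors): %d nodes, %d edges\n",
              x$mode, x$anchor_mode, length(x$estimates),
              nrow(x$residuals)))
  est <- data.frame(node = names(x$estimates),
                    estimate = round(x$estimates, 2),
                    uncertainty_2sigma = round(x$uncertainty_2sigma, 2),
                    row.names = NULL)
  print(est)
  cat(sprintf("objective: %.4g\n", x$objective))
  invisible(x)
}
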