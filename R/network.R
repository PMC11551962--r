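# Graph data model for free-energy networks. Two modes:
#   "complex"     - nodes are receptor-ligand complexes (values are ABFEs);
#                   RBFE edges join complexes sharing a receptor, RHFE edges
#                   join complexes sharing a ligand.
#   "selectivity" - nodes are per-ligand binding selectivity free energies
#                   for one ordered receptor pair; RSFE edges join them.
# Edges are directed with the convention value = x(head) - x(tail); files
# and constructors always state the direction explicitly, no sign guessing.

.node_sep <- ":"

#' Node identifier of a receptor-ligand complex
#'
#' Complex-mode networks identify nodes as `"receptor:ligand"`. Identifiers
#' are opaque, case-sensitive strings with no chemistry awareness; the only
#' restriction is that they may not contain the `":"` separator.
#'
#' @param receptor,ligand Character vectors of identifiers.
#' @return Character vector of node ids.
#' @examples
#' complex_node_id("TEMOA", "G1")
#' @export
complex_node_id <- function(receptor, ligand) {
  .check_id(receptor, "receptor")
  .check_id(ligand, "ligand")
  paste(receptor, ligand, sep = .node_sep)
}

.check_id <- function(id, what) {
  if (!is.character(id) || any(is.na(id)) || any(!nzchar(id)))
    stop(what, " identifiers must be non-empty strings")
  if (any(grepl(.node_sep, id, fixed = TRUE)))
    stop(what, " identifiers may not contain '", .node_sep, "'")
  invisible(id)
}

.split_complex_id <- function(id) {
  parts <- strsplit(id, .node_sep, fixed = TRUE)
  list(receptor = vapply(parts, `[`, "", 1L),
       ligand = vapply(parts, `[`, "", 2L))
}

.empty_edges <- function() {
  data.frame(kind = character(), tail = character(), head = character(),
             value = numeric(), uncertainty = numeric(),
             stringsAsFactors = FALSE)
}

.empty_anchors <- function() {
  data.frame(node = character(), value = numeric(), uncertainty = numeric(),
             stringsAsFactors = FALSE)
}

#' Create an empty free-energy network
#'
#' @param mode `"complex"` for ABFE estimation over receptor-ligand
#'   complexes, or `"selectivity"` for BSFE estimation over ligands of one
#'   ordered receptor pair.
#' @param receptors For selectivity mode, a length-2 character vector
#'   `c(from, to)` naming the ordered receptor pair all nodes share.
#' @return An object of class `fe_network` with fields `mode`, `receptors`,
#'   `edges` and `anchors`.
#' @seealso [add_rbfe()], [add_rhfe()], [add_rsfe()], [add_anchor()],
#'   [validate_network()], [solve_network()]
#' @examples
#' net <- fe_network("complex")
#' net <- add_rbfe(net, "TEMOA", "G1", "G2p", measurement(-5.08, 0.32))
#' net <- add_anchor(net, value = measurement(-6.65, 0.32),
#'                   receptor = "TEMOA", ligand = "G1")
#' net
#' @export
fe_network <- function(mode = c("complex", "selectivity"), receptors = NULL) {
  mode <- match.arg(mode)
  if (mode == "selectivity") {
    if (is.null(receptors) || length(receptors) != 2L)
      stop("selectivity networks need 'receptors = c(from, to)'")
    .check_id(receptors, "receptor")
    if (receptors[1L] == receptors[2L])
      stop("the ordered receptor pair must name two distinct receptors")
  } else if (!is.null(receptors)) {
    stop("'receptors' applies only to selectivity mode")
  }
  structure(list(mode = mode, receptors = receptors,
                 edges = .empty_edges(), anchors = .empty_anchors()),
            class = "fe_network")
}

.check_network <- function(network) {
  if (!inherits(network, "fe_network"))
    stop("expected a 'fe_network' object")
  invisible(network)
}

.scalar_measurement <- function(m, what = "measurement") {
  m <- .as_measurement(m, what)
  if (length(m) != 1L) stop(what, " must have length 1")
  m
}

.append_edge <- function(network, kind, tail, head, m) {
  if (tail == head)
    stop("structure error: edge endpoints must differ (", tail, ")")
  network$edges <- rbind(network$edges, data.frame(
    kind = kind, tail = tail, head = head,
    value = m$value, uncertainty = m$uncertainty,
    stringsAsFactors = FALSE))
  rownames(network$edges) <- NULL
  network
}

#' Add a relative binding free-energy edge
#'
#' Adds an RBFE measurement for the ordered ligand pair
#' `ligand_from -> ligand_to` on one receptor. The edge runs from the
#' complex with `ligand_from` to the complex with `ligand_to`, so the
#' measured value is `ABFE(receptor, ligand_to) - ABFE(receptor,
#' ligand_from)`.
#'
#' @param network A complex-mode [fe_network()].
#' @param receptor Receptor shared by both complexes.
#' @param ligand_from,ligand_to The ordered ligand pair.
#' @param m The measured RBFE as a [measurement()] (kcal/mol, 2-sigma
#'   uncertainty).
#' @return The network with the edge appended.
#' @export
add_rbfe <- function(network, receptor, ligand_from, ligand_to, m) {
  .check_network(network)
  if (network$mode != "complex")
    stop("structure error: RBFE edges belong to complex-mode networks")
  m <- .scalar_measurement(m, "RBFE")
  .append_edge(network, "RBFE",
               complex_node_id(receptor, ligand_from),
               complex_node_id(receptor, ligand_to), m)
}

#' Add a receptor-hopping free-energy edge
#'
#' Adds an RHFE (directly calculated BSFE) measurement for one ligand
#' hopping from `receptor_from` to `receptor_to`. The edge value is
#' `ABFE(receptor_to, ligand) - ABFE(receptor_from, ligand)`. Hopping
#' edges are what tie the per-receptor RBFE subnetworks onto a common
#' free-energy scale.
#'
#' @param network A complex-mode [fe_network()].
#' @param ligand Ligand being transferred.
#' @param receptor_from,receptor_to The ordered receptor pair.
#' @param m The measured RHFE as a [measurement()].
#' @return The network with the edge appended.
#' @export
add_rhfe <- function(network, ligand, receptor_from, receptor_to, m) {
  .check_network(network)
  if (network$mode != "complex")
    stop("structure error: RHFE edges belong to complex-mode networks")
  m <- .scalar_measurement(m, "RHFE")
  .append_edge(network, "RHFE",
               complex_node_id(receptor_from, ligand),
               complex_node_id(receptor_to, ligand), m)
}

#' Add a receptor-swapping free-energy edge
#'
#' Adds an RSFE measurement for swapping `ligand_1` and `ligand_2` across
#' the network's ordered receptor pair (A, B), starting from ligand 1
#' bound to A and ligand 2 bound to B. Since
#' `RSFE = BSFE(ligand_1) - BSFE(ligand_2)`, the edge runs from the
#' `ligand_2` node to the `ligand_1` node.
#'
#' @param network A selectivity-mode [fe_network()].
#' @param ligand_1 Ligand starting in the first-listed receptor.
#' @param ligand_2 Ligand starting in the second-listed receptor.
#' @param m The measured RSFE as a [measurement()].
#' @return The network with the edge appended.
#' @export
add_rsfe <- function(network, ligand_1, ligand_2, m) {
  .check_network(network)
  if (network$mode != "selectivity")
    stop("structure error: RSFE edges belong to selectivity-mode networks")
  .check_id(c(ligand_1, ligand_2), "ligand")
  m <- .scalar_measurement(m, "RSFE")
  .append_edge(network, "RSFE", ligand_2, ligand_1, m)
}

#' Anchor a node at a reference value
#'
#' Anchors fix the absolute scale of a difference network: a complex-mode
#' network is anchored at the known ABFE of a reference complex, a
#' selectivity network at the known BSFE of a reference ligand. By default
#' the solver treats anchors as hard equality constraints; see
#' [solve_network()] for the soft alternative.
#'
#' @param network A [fe_network()].
#' @param value Reference value as a [measurement()]; its uncertainty (if
#'   any) is reported for the anchored node but does not enter the hard
#'   solve.
#' @param receptor,ligand Identify the node: both for complex mode, only
#'   `ligand` for selectivity mode.
#' @return The network with the anchor appended.
#' @export
add_anchor <- function(network, value, receptor = NULL, ligand) {
  .check_network(network)
  value <- .scalar_measurement(value, "anchor")
  if (network$mode == "complex") {
    if (is.null(receptor))
      stop("complex-mode anchors need both 'receptor' and 'ligand'")
    node <- complex_node_id(receptor, ligand)
  } else {
    if (!is.null(receptor))
      stop("selectivity-mode anchors are identified by 'ligand' only")
    .check_id(ligand, "ligand")
    node <- ligand
  }
  if (node %in% network$anchors$node &&
      any(abs(network$anchors$value[network$anchors$node == node] -
              value$value) > 1e-12))
    stop("conflicting anchors for node ", node)
  network$anchors <- rbind(network$anchors, data.frame(
    node = node, value = value$value, uncertainty = value$uncertainty,
    stringsAsFactors = FALSE))
  rownames(network$anchors) <- NULL
  network
}

#' Nodes of a network
#'
#' @param network A [fe_network()].
#' @return Character vector of node identifiers (edge endpoints plus
#'   anchored nodes), in first-appearance order.
#' @export
network_nodes <- function(network) {
  .check_network(network)
  unique(c(rbind(network$edges$tail, network$edges$head),
           network$anchors$node))
}

.components <- function(network) {
  nodes <- network_nodes(network)
  if (length(nodes) == 0L) return(integer(0))
  comp <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (comp[[i]] != i) i <- comp[[i]]; i }
  for (k in seq_len(nrow(network$edges))) {
    i <- find(match(network$edges$tail[k], nodes))
    j <- find(match(network$edges$head[k], nodes))
    if (i != j) comp[j] <- i
  }
  stats::setNames(vapply(seq_along(nodes), find, 0L), nodes)
}

#' Structural validation of a free-energy network
#'
#' Checks that the network is solvable before any factorization is
#' attempted. Findings are returned as data, not raised: an empty result
#' means the network is structurally sound.
#'
#' Checks performed: every connected component (edges taken as undirected)
#' contains at least one anchor; edge kinds match the network mode; RBFE
#' edges join complexes sharing a receptor and RHFE edges complexes
#' sharing a ligand; parallel zero-uncertainty edges do not contradict
#' each other.
#'
#' @param network A [fe_network()].
#' @return Character vector of findings; `character(0)` if none.
#' @export
validate_network <- function(network) {
  .check_network(network)
  findings <- character(0)
  e <- network$edges
  ok_kinds <- if (network$mode == "complex") c("RBFE", "RHFE") else "RSFE"
  bad <- !e$kind %in% ok_kinds
  if (any(bad))
    findings <- c(findings, paste0("edge ", which(bad), ": kind ",
                                   e$kind[bad], " not allowed in ",
                                   network$mode, " mode"))
  if (network$mode == "complex" && nrow(e) > 0L) {
    t <- .split_complex_id(e$tail); h <- .split_complex_id(e$head)
    bad <- e$kind == "RBFE" & t$receptor != h$receptor
    if (any(bad))
      findings <- c(findings, paste0("edge ", which(bad),
                                     ": RBFE endpoints on different receptors"))
    bad <- e$kind == "RHFE" & t$ligand != h$ligand
    if (any(bad))
      findings <- c(findings, paste0("edge ", which(bad),
                                     ": RHFE endpoints with different ligands"))
  }
  comp <- .components(network)
  anchored <- unique(comp[network$anchors$node])
  for (c_id in unique(comp)) {
    if (!c_id %in% anchored) {
      members <- names(comp)[comp == c_id]
      findings <- c(findings,
                    paste0("component without anchor: ",
                           paste(members, collapse = ", ")))
    }
  }
  # contradictory exact (zero-uncertainty) parallel edges
  exact <- which(!is.na(e$uncertainty) & e$uncertainty == 0)
  if (length(exact) > 1L) {
    key <- ifelse(e$tail[exact] < e$head[exact],
                  paste(e$tail[exact], e$head[exact]),
                  paste(e$head[exact], e$tail[exact]))
    oriented <- ifelse(e$tail[exact] < e$head[exact],
                       e$value[exact], -e$value[exact])
    for (k in unique(key[duplicated(key)])) {
      v <- oriented[key == k]
      if (diff(range(v)) > 1e-12)
        findings <- c(findings,
                      paste0("contradictory zero-uncertainty parallel edges: ",
                             k))
    }
  }
  findings
}

#' @export
print.fe_network <- function(x, ...) {
  cat(sprintf("Free-energy network (%s mode): %d nodes, %d edges, %d anchors\n",
              x$mode, length(network_nodes(x)), nrow(x$edges),
              nrow(x$anchors)))
  if (!is.null(x$receptors))
    cat(sprintf("  receptor pair: %s -> %s\n",
                x$receptors[1L], x$receptors[2L]))
  if (nrow(x$edges) > 0L) {
    tab <- table(x$edges$kind)
    cat("  edges: ",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
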