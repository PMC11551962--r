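# Edge-list and anchor file input/output plus JSON reports.
#
# Edge-list schema (tab-separated, header row):
#   kind  receptor_a  ligand_a  receptor_b  ligand_b  value_kcal_mol
#   uncertainty_2sigma
# RBFE rows require receptor_a == receptor_b (edge ligand_a -> ligand_b on
# that receptor); RHFE rows require ligand_a == ligand_b (hop receptor_a ->
# receptor_b); RSFE rows carry the ordered receptor pair in
# receptor_a/receptor_b and the swap pair (ligand_a starts in receptor_a).
#
# Anchor schema: receptor  ligand  value_kcal_mol  uncertainty_2sigma,
# with an empty receptor field for selectivity-mode (per-ligand) anchors.
# Anchors live in their own file to keep the edge schema uniform.

.edge_cols <- c("kind", "receptor_a", "ligand_a", "receptor_b", "ligand_b",
                "value_kcal_mol", "uncertainty_2sigma")
.anchor_cols <- c("receptor", "ligand", "value_kcal_mol",
                  "uncertainty_2sigma")

#' Read and validate an edge-list file
#'
#' Parses a delimiter-separated edge list and checks every row: known
#' kind, finite value, non-negative uncertainty (may be empty), and the
#' per-kind endpoint constraints. Malformed rows are reported with their
#' row numbers.
#'
#' @param path Path to the file.
#' @param sep Field separator (default tab).
#' @return A data frame with the edge-list columns, one row per edge, in
#'   file order.
#' @seealso [network_from_edge_list()] to turn the rows into a
#'   [fe_network()].
#' @export
read_edge_list <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", comment.char = "#")
  missing <- setdiff(.edge_cols, names(df))
  if (length(missing) > 0L)
    stop("edge list ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  df <- df[.edge_cols]
  if (nrow(df) == 0L) {
    df$value_kcal_mol <- numeric(0)
    df$uncertainty_2sigma <- numeric(0)
    return(df)
  }
  v <- suppressWarnings(as.numeric(df$value_kcal_mol))
  u <- suppressWarnings(as.numeric(ifelse(nzchar(trimws(df$uncertainty_2sigma)),
                                          df$uncertainty_2sigma, NA)))
  problems <- character(0)
  row_err <- function(rows, msg)
    if (any(rows)) paste0("row ", which(rows), ": ", msg)
  problems <- c(problems,
    row_err(!df$kind %in% c("RBFE", "RHFE", "RSFE"), "unknown kind"),
    row_err(!is.finite(v), "non-numeric value"),
    row_err(!is.na(u) & (!is.finite(u) | u < 0),
            "uncertainty must be a non-negative number"),
    row_err(df$kind == "RBFE" & df$receptor_a != df$receptor_b,
            "RBFE rows need receptor_a == receptor_b"),
    row_err(df$kind == "RHFE" & df$ligand_a != df$ligand_b,
            "RHFE rows need ligand_a == ligand_b"))
  if (length(problems) > 0L)
    stop("parse errors in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  df$value_kcal_mol <- v
  df$uncertainty_2sigma <- u
  df
}

#' Read an anchor file
#'
#' @param path Path to the file.
#' @param sep Field separator (default tab).
#' @return A data frame with columns `receptor` (possibly empty),
#'   `ligand`, `value_kcal_mol`, `uncertainty_2sigma`.
#' @export
read_anchor_list <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", comment.char = "#")
  missing <- setdiff(.anchor_cols, names(df))
  if (length(missing) > 0L)
    stop("anchor file ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  df <- df[.anchor_cols]
  v <- suppressWarnings(as.numeric(df$value_kcal_mol))
  if (any(!is.finite(v)))
    stop("parse errors in ", path, ": row ",
         paste(which(!is.finite(v)), collapse = ", "),
         ": non-numeric anchor value")
  df$value_kcal_mol <- v
  df$uncertainty_2sigma <-
    suppressWarnings(as.numeric(ifelse(nzchar(trimws(df$uncertainty_2sigma)),
                                       df$uncertainty_2sigma, NA)))
  df
}

#' Build a network from edge-list (and anchor) rows
#'
#' The network mode is inferred from the edge kinds: RSFE rows give a
#' selectivity network (all rows must then be RSFE and share one ordered
#' receptor pair); RBFE/RHFE rows give a complex network. Mixing the two
#' families is an error.
#'
#' @param edges Data frame as returned by [read_edge_list()].
#' @param anchors Optional data frame as returned by
#'   [read_anchor_list()].
#' @return A [fe_network()].
#' @export
network_from_edge_list <- function(edges, anchors = NULL) {
  if (nrow(edges) == 0L && is.null(anchors))
    stop("cannot infer a network from zero edges and no anchors")
  selectivity <- any(edges$kind == "RSFE")
  if (selectivity && any(edges$kind != "RSFE"))
    stop("RSFE edges cannot be mixed with RBFE/RHFE edges")
  if (selectivity) {
    rp <- unique(edges[c("receptor_a", "receptor_b")])
    if (nrow(rp) > 1L)
      stop("a selectivity network supports one ordered receptor pair; got ",
           nrow(rp))
    net <- fe_network("selectivity",
                      receptors = c(rp$receptor_a, rp$receptor_b))
    for (k in seq_len(nrow(edges)))
      net <- add_rsfe(net, edges$ligand_a[k], edges$ligand_b[k],
                      measurement(edges$value_kcal_mol[k],
                                  edges$uncertainty_2sigma[k]))
  } else {
    net <- fe_network("complex")
    for (k in seq_len(nrow(edges))) {
      m <- measurement(edges$value_kcal_mol[k], edges$uncertainty_2sigma[k])
      if (edges$kind[k] == "RBFE")
        net <- add_rbfe(net, edges$receptor_a[k], edges$ligand_a[k],
                        edges$ligand_b[k], m)
      else
        net <- add_rhfe(net, edges$ligand_a[k], edges$receptor_a[k],
                        edges$receptor_b[k], m)
    }
  }
  if (!is.null(anchors)) {
    for (k in seq_len(nrow(anchors))) {
      m <- measurement(anchors$value_kcal_mol[k],
                       anchors$uncertainty_2sigma[k])
      r <- anchors$receptor[k]
      if (net$mode == "complex") {
        if (is.na(r) || !nzchar(r))
          stop("anchor row ", k, ": complex-mode anchors need a receptor")
        net <- add_anchor(net, m, receptor = r, ligand = anchors$ligand[k])
      } else {
        net <- add_anchor(net, m, ligand = anchors$ligand[k])
      }
    }
  }
  net
}

#' Convert a network back to edge-list and anchor rows
#'
#' Inverse of [network_from_edge_list()]: round-trips field-exactly.
#'
#' @param network A [fe_network()].
#' @return A list with data frames `edges` and `anchors` in the file
#'   schemas.
#' @export
network_to_edge_list <- function(network) {
  .check_network(network)
  e <- network$edges
  if (network$mode == "complex") {
    t <- .split_complex_id(e$tail); h <- .split_complex_id(e$head)
    edges <- data.frame(kind = e$kind, receptor_a = t$receptor,
                        ligand_a = t$ligand, receptor_b = h$receptor,
                        ligand_b = h$ligand, value_kcal_mol = e$value,
                        uncertainty_2sigma = e$uncertainty,
                        stringsAsFactors = FALSE)
    a <- .split_complex_id(network$anchors$node)
    anchors <- data.frame(receptor = a$receptor, ligand = a$ligand,
                          value_kcal_mol = network$anchors$value,
                          uncertainty_2sigma = network$anchors$uncertainty,
                          stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(kind = e$kind,
                        receptor_a = rep(network$receptors[1L], nrow(e)),
                        ligand_a = e$head,  # ligand 1 starts in receptor A
                        receptor_b = rep(network$receptors[2L], nrow(e)),
                        ligand_b = e$tail,
                        value_kcal_mol = e$value,
                        uncertainty_2sigma = e$uncertainty,
                        stringsAsFactors = FALSE)
    anchors <- data.frame(receptor = rep("", nrow(network$anchors)),
                          ligand = network$anchors$node,
                          value_kcal_mol = network$anchors$value,
                          uncertainty_2sigma = network$anchors$uncertainty,
                          stringsAsFactors = FALSE)
  }
  list(edges = edges, anchors = anchors)
}

#' Write edge-list or anchor rows to a file
#'
#' @param df Data frame in the edge-list or anchor schema.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(df, path, sep = "\t") {
  out <- df
  num <- vapply(out, is.numeric, TRUE)
  for (j in which(num))
    out[[j]] <- ifelse(is.na(out[[j]]), "",
                       format(out[[j]], digits = 17, trim = TRUE,
                              scientific = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a solved network as a JSON report
#'
#' The report stores full-precision numbers (display rounding is left to
#' the reader), per-node estimates with 2-sigma uncertainties, per-edge
#' residuals, the objective, and provenance: package version, MD5 of any
#' input files, and the seed if one was used. No timestamp is written, so
#' identical inputs give byte-identical reports.
#'
#' @param fit A `diffnet_fit` from [solve_network()].
#' @param path Output path.
#' @param inputs Optional character vector of input file paths to hash.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, inputs = NULL, seed = NULL) {
  if (!inherits(fit, "diffnet_fit")) stop("expected a 'diffnet_fit'")
  prov <- list(package = "bsfenet",
               version = as.character(utils::packageVersion("bsfenet")))
  if (!is.null(inputs))
    prov$inputs <- lapply(stats::setNames(inputs, basename(inputs)),
                          function(p) unname(tools::md5sum(p)))
  if (!is.null(seed)) prov$seed <- seed
  payload <- list(
    mode = fit$mode,
    anchor_mode = fit$anchor_mode,
    receptors = fit$receptors,
    estimates = as.list(fit$estimates),
    uncertainty_2sigma = as.list(fit$uncertainty_2sigma),
    residuals = fit$residuals,
    objective = fit$objective,
    condition_number = fit$condition_number,
    anchors = fit$anchors,
    provenance = prov)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()].
#' @return The report as a list; `estimates` and `uncertainty_2sigma` as
#'   named numeric vectors.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$estimates <- unlist(rep$estimates)
  rep$uncertainty_2sigma <-
    vapply(rep$uncertainty_2sigma, function(x)
      if (is.null(x)) NA_real_ else as.double(x), 0)
  rep
}
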