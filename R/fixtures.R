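# Packaged benchmark tables: the SAMPL8 host-guest measurements for the
# TEMOA and TEETOA hosts (absolute, relative, hopping and swapping free
# energies for guests G1, G2p, G3, G4, G5) and the benzamidine (Bz) /
# 1-amidinopiperidine (Am) relative and swapping measurements for the
# trypsin/thrombin serine proteases. Each load is verified against a
# stored row count and value checksum.

.fixture_checksums <- list(
  sampl8_abfe = list(rows = 10L, sum = -59.39),
  sampl8_rhfe = list(rows = 5L, sum = 26.36),
  sampl8_rbfe = list(rows = 20L, sum = 3.27),
  sampl8_rsfe = list(rows = 10L, sum = -3.58),
  trypsin_thrombin_rbfe = list(rows = 2L, sum = 2.52),
  trypsin_thrombin_rsfe = list(rows = 2L, sum = -0.51))

#' Packaged benchmark measurement tables
#'
#' Returns one of the packaged free-energy tables by name:
#' \describe{
#'   \item{`sampl8_abfe`}{Absolute binding free energies of the five
#'     SAMPL8 guests to TEMOA and TEETOA (columns `receptor`, `ligand`,
#'     `value_kcal_mol`, `uncertainty_2sigma`).}
#'   \item{`sampl8_rhfe`}{Receptor-hopping free energies TEMOA -> TEETOA,
#'     one per guest, in the edge-list schema.}
#'   \item{`sampl8_rbfe`}{Relative binding free energies for all guest
#'     pairs on each host (20 edges).}
#'   \item{`sampl8_rsfe`}{Receptor-swapping free energies for all guest
#'     pairs across the two hosts (10 edges).}
#'   \item{`trypsin_thrombin_rbfe`}{RBFEs of Bz/Am on trypsin and
#'     thrombin.}
#'   \item{`trypsin_thrombin_rsfe`}{Forward and reverse swap free
#'     energies of Bz/Am across trypsin and thrombin.}
#' }
#' All uncertainties are 2-sigma; all values kcal/mol. Each table is
#' checked against a stored row count and value checksum on load.
#'
#' @param name One of the names above.
#' @return A data frame (edge-list schema except `sampl8_abfe`).
#' @examples
#' fixtures("sampl8_abfe")
#' @export
fixtures <- function(name) {
  if (!name %in% names(.fixture_checksums))
    stop("unknown fixture: ", name, "; available: ",
         paste(names(.fixture_checksums), collapse = ", "))
  path <- system.file("extdata", paste0(name, ".tsv"), package = "bsfenet",
                      mustWork = TRUE)
  df <- if (name == "sampl8_abfe") {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    out
  } else {
    read_edge_list(path)
  }
  chk <- .fixture_checksums[[name]]
  if (nrow(df) != chk$rows ||
      abs(sum(df$value_kcal_mol) - chk$sum) > 1e-9)
    stop("fixture ", name, " failed its integrity check")
  df
}

#' ABFE measurements of the host-guest benchmark
#'
#' @param receptor Host name (`"TEMOA"` or `"TEETOA"`).
#' @param ligand Guest name (`"G1"`, `"G2p"`, `"G3"`, `"G4"`, `"G5"`).
#' @return A [measurement()] for that complex.
#' @export
sampl8_abfe <- function(receptor, ligand) {
  tab <- fixtures("sampl8_abfe")
  row <- tab[tab$receptor == receptor & tab$ligand == ligand, ]
  if (nrow(row) != 1L)
    stop("no ABFE for ", receptor, " / ", ligand)
  measurement(row$value_kcal_mol, row$uncertainty_2sigma)
}

#' Host-guest benchmark networks, assembled
#'
#' `sampl8_network()` builds the two-host complex-mode network from the 20
#' RBFE edges plus the requested hopping edges, anchored at the ABFE of G1
#' bound to TEMOA. `sampl8_selectivity_network()` builds the
#' TEMOA -> TEETOA selectivity network from the 10 swap edges, anchored at
#' the directly calculated hopping free energy of G1.
#'
#' @param rhfe_guests Guests whose hopping edges are included; `NULL`
#'   (default) includes all five.
#' @return A [fe_network()] ready for [solve_network()] /
#'   [solve_selectivity()].
#' @examples
#' fit <- solve_network(sampl8_network())
#' round(fit$estimates["TEMOA:G2p"], 2)
#' @export
sampl8_network <- function(rhfe_guests = NULL) {
  rbfe <- fixtures("sampl8_rbfe")
  rhfe <- fixtures("sampl8_rhfe")
  if (!is.null(rhfe_guests)) {
    unknown <- setdiff(rhfe_guests, rhfe$ligand_a)
    if (length(unknown) > 0L)
      stop("unknown guests: ", paste(unknown, collapse = ", "))
    rhfe <- rhfe[rhfe$ligand_a %in% rhfe_guests, ]
  }
  net <- network_from_edge_list(rbind(rbfe, rhfe))
  add_anchor(net, sampl8_abfe("TEMOA", "G1"),
             receptor = "TEMOA", ligand = "G1")
}

#' @rdname sampl8_network
#' @export
sampl8_selectivity_network <- function() {
  rsfe <- fixtures("sampl8_rsfe")
  rhfe <- fixtures("sampl8_rhfe")
  net <- network_from_edge_list(rsfe)
  g1 <- rhfe[rhfe$ligand_a == "G1", ]
  add_anchor(net, measurement(g1$value_kcal_mol, g1$uncertainty_2sigma),
             ligand = "G1")
}
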