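# Thermodynamic identity algebra relating absolute binding free energies
# (ABFE), relative binding free energies (RBFE), binding selectivity /
# receptor-hopping free energies (BSFE = RHFE) and receptor-swapping free
# energies (RSFE). All identities are simple signed sums, so first-order
# uncertainty propagation is quadrature; it is performed directly on the
# reported 2-sigma scale, which quadrature leaves invariant.

#' Difference of two free-energy measurements
#'
#' Computes `final - initial` with quadrature propagation of the reported
#' uncertainties. This is the elementary operation behind all the derived
#' quantities: an RBFE is a difference of two ABFEs on the same receptor, a
#' BSFE is a difference of one ligand's ABFEs on two receptors, and an RSFE
#' is a difference of RBFEs or of BSFEs.
#'
#' @param final,initial `fe_measurement` objects (or bare numerics, taken
#'   as values without uncertainty).
#' @return A `fe_measurement`; its uncertainty is
#'   `sqrt(final$uncertainty^2 + initial$uncertainty^2)` and is `NA`
#'   whenever either input's uncertainty is absent.
#' @examples
#' # BSFE of a guest from its two absolute binding free energies
#' difference(measurement(-8.23, 0.26), measurement(-12.10, 0.26))
#' @export
difference <- function(final, initial) {
  final <- .as_measurement(final, "final")
  initial <- .as_measurement(initial, "initial")
  measurement(final$value - initial$value,
              sqrt(final$uncertainty^2 + initial$uncertainty^2))
}

#' Receptor-hopping (binding selectivity) free energy from two ABFEs
#'
#' The binding selectivity free energy (BSFE) of a ligand for receptor B
#' over receptor A is the difference of its standard binding free energies,
#' `ABFE(B) - ABFE(A)`. It equals the free energy of transferring the bound
#' ligand from A's binding site to B's (receptor hopping), so a directly
#' calculated RHFE estimates the same quantity.
#'
#' @param abfe_A ABFE of the complex with the starting receptor A.
#' @param abfe_B ABFE of the complex with the destination receptor B.
#' @return The BSFE for the hop A -> B as a `fe_measurement`.
#' @examples
#' rhfe_from_abfes(measurement(-12.10, 0.26), measurement(-8.23, 0.26))
#' @export
rhfe_from_abfes <- function(abfe_A, abfe_B) difference(abfe_B, abfe_A)

#' Receptor-swapping free energy from two RBFEs
#'
#' The free energy for swapping two ligands across two receptors, starting
#' from ligand 1 bound to receptor A and ligand 2 bound to receptor B, is
#' the difference of the relative binding free energies of the ordered pair
#' L1 -> L2 on the two receptors: `RBFE_A(L1 -> L2) - RBFE_B(L1 -> L2)`.
#'
#' @param rbfe_A RBFE of the ligand pair L1 -> L2 on receptor A.
#' @param rbfe_B RBFE of the same ordered pair on receptor B.
#' @return The RSFE for the swap as a `fe_measurement`.
#' @examples
#' rsfe_from_rbfes(measurement(2.19, 0.32), measurement(-0.33, 0.32))
#' @export
rsfe_from_rbfes <- function(rbfe_A, rbfe_B) difference(rbfe_A, rbfe_B)

#' Receptor-swapping free energy from two BSFEs
#'
#' Equivalent second decomposition of the swap free energy: with both
#' selectivity free energies oriented for the hop A -> B,
#' `RSFE = BSFE(L1) - BSFE(L2)`.
#'
#' @param bsfe_L1 BSFE of ligand 1 for the hop A -> B.
#' @param bsfe_L2 BSFE of ligand 2 for the same ordered receptor pair.
#' @return The RSFE for the swap starting from (L1 at A, L2 at B).
#' @examples
#' rsfe_from_bsfes(measurement(5.46, 0.34), measurement(3.93, 0.24))
#' @export
rsfe_from_bsfes <- function(bsfe_L1, bsfe_L2) difference(bsfe_L1, bsfe_L2)

#' Selectivity coefficient from a binding selectivity free energy
#'
#' The selectivity coefficient of a ligand for receptor B over receptor A
#' is the ratio of its binding constants, `Kb(B)/Kb(A)`, and is related to
#' the BSFE for the hop A -> B by `s = exp(-BSFE / kT)`. Because the free
#' energy enters exponentially, the uncertainty is multiplicative: the
#' returned `uncertainty_factor` is `exp(sigma / kT)` with
#' `sigma = uncertainty / 2`, so a one-sigma band is
#' `[s / factor, s * factor]`.
#'
#' @param bsfe BSFE for the hop A -> B (`fe_measurement` or numeric,
#'   kcal/mol).
#' @param ctx A [thermo_context()].
#' @return A list with numeric vectors `coefficient` and
#'   `uncertainty_factor` (the latter `NA` when the BSFE has no
#'   uncertainty).
#' @examples
#' selectivity_coefficient(measurement(5.46, 0.34))
#' @export
selectivity_coefficient <- function(bsfe, ctx = thermo_context()) {
  bsfe <- .as_measurement(bsfe, "bsfe")
  kT <- .kT(ctx)
  list(coefficient = exp(-bsfe$value / kT),
       uncertainty_factor = exp((bsfe$uncertainty / 2) / kT))
}

#' Ratio of two ligands' selectivity coefficients from an RSFE
#'
#' For a swap starting from (L1 at receptor A, L2 at receptor B), the
#' receptor-swapping free energy gives the ratio of selectivity
#' coefficients of the two ligands for receptor A over receptor B:
#' `s(L1; A over B) / s(L2; A over B) = exp(+RSFE / kT)`.
#'
#' @param rsfe RSFE for the swap (`fe_measurement` or numeric, kcal/mol).
#' @param ctx A [thermo_context()].
#' @return A list with `ratio` and multiplicative `uncertainty_factor`.
#' @examples
#' selectivity_ratio_from_rsfe(measurement(2.625))
#' @export
selectivity_ratio_from_rsfe <- function(rsfe, ctx = thermo_context()) {
  rsfe <- .as_measurement(rsfe, "rsfe")
  kT <- .kT(ctx)
  list(ratio = exp(rsfe$value / kT),
       uncertainty_factor = exp((rsfe$uncertainty / 2) / kT))
}

#' Binding free energy from a pKi
#'
#' Converts an inhibition constant expressed as `pKi = -log10(Ki)` into a
#' standard binding free energy, `dG = -kB T pKi ln(10)` kcal/mol, treating
#' Ki as an estimate of the dissociation constant.
#'
#' @param pki Numeric vector of pKi values.
#' @param ctx A [thermo_context()]; experimental affinities are usually
#'   converted at `temperature = 298.15`.
#' @return A `fe_measurement` without uncertainty.
#' @examples
#' # benzamidine/trypsin at room temperature
#' dg_from_pki(7.51, thermo_context(298.15))
#' @export
dg_from_pki <- function(pki, ctx = thermo_context()) {
  if (!is.numeric(pki) || any(!is.finite(pki)))
    stop("pki must be finite numeric")
  measurement(-.kT(ctx) * pki * log(10))
}

#' Binding free energy from a binding constant, and back
#'
#' `dg_from_kb()` applies `dG = -kB T ln(Kb)`; `kb_from_dg()` inverts it.
#' The two are exact inverses to machine precision.
#'
#' @param kb Numeric vector of binding constants; must be positive.
#' @param dg Free energy (`fe_measurement` or numeric, kcal/mol).
#' @param ctx A [thermo_context()].
#' @return `dg_from_kb()` returns a `fe_measurement`; `kb_from_dg()`
#'   returns a numeric vector.
#' @examples
#' dg_from_kb(1e6)
#' kb_from_dg(dg_from_kb(1e6))
#' @export
dg_from_kb <- function(kb, ctx = thermo_context()) {
  if (!is.numeric(kb) || any(!is.finite(kb)) || any(kb <= 0))
    stop("binding constant must be positive and finite")
  measurement(-.kT(ctx) * log(kb))
}

#' @rdname dg_from_kb
#' @export
kb_from_dg <- function(dg, ctx = thermo_context()) {
  dg <- .as_measurement(dg, "dg")
  exp(-dg$value / .kT(ctx))
}
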