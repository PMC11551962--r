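# Boltzmann constant in kcal/(mol K)
.kB <- 0.0019872041

#' Free-energy measurement with reported uncertainty
#'
#' A `fe_measurement` carries one or more free-energy values in kcal/mol
#' together with their reported uncertainties. Throughout the package,
#' uncertainties follow the common reporting convention of alchemical
#' free-energy tables: they are *twice* the standard deviation (2-sigma).
#' Quadrature propagation is scale invariant, so sums and differences of
#' measurements can be propagated directly on the 2-sigma scale; solver
#' weights (see [solve_network()]) divide by two to recover sigma.
#'
#' Experimental values often come without an error bar; an absent
#' uncertainty (`NA`) propagates as absent, never as zero.
#'
#' @param value Numeric vector of free energies (kcal/mol). Must be finite.
#' @param uncertainty Numeric vector of 2-sigma uncertainties (kcal/mol),
#'   `NA` where unreported. Must be finite and non-negative where present.
#' @return An object of class `fe_measurement` with fields `value` and
#'   `uncertainty`, both numeric vectors of common length.
#' @examples
#' m <- measurement(-12.10, 0.26)
#' m
#' @export
measurement <- function(value, uncertainty = NA_real_) {
  if (!is.numeric(value) || length(value) == 0L)
    stop("invalid measurement: 'value' must be a non-empty numeric vector")
  if (!is.numeric(uncertainty) && !all(is.na(uncertainty)))
    stop("invalid measurement: 'uncertainty' must be numeric or NA")
  n <- max(length(value), length(uncertainty))
  value <- rep_len(as.double(value), n)
  uncertainty <- rep_len(as.double(uncertainty), n)
  if (any(!is.finite(value)))
    stop("invalid measurement: non-finite free-energy value")
  bad <- !is.na(uncertainty) & (!is.finite(uncertainty) | uncertainty < 0)
  if (any(bad))
    stop("invalid measurement: uncertainty must be finite and >= 0")
  structure(list(value = value, uncertainty = uncertainty),
            class = "fe_measurement")
}

#' @export
length.fe_measurement <- function(x) length(x$value)

#' @export
`[.fe_measurement` <- function(x, i) measurement(x$value[i], x$uncertainty[i])

#' @export
format.fe_measurement <- function(x, digits = 2, ...) {
  v <- formatC(round(x$value, digits), format = "f", digits = digits)
  u <- ifelse(is.na(x$uncertainty), "",
              paste0(" ± ", formatC(round(x$uncertainty, digits),
                                         format = "f", digits = digits)))
  paste0(v, u)
}

#' @export
print.fe_measurement <- function(x, ...) {
  cat(paste0(format(x), " kcal/mol"), sep = "\n")
  invisible(x)
}

.as_measurement <- function(x, what = "measurement") {
  if (inherits(x, "fe_measurement")) return(x)
  if (is.numeric(x)) return(measurement(x))
  stop("invalid ", what, ": expected a 'fe_measurement' or a numeric value")
}

#' Thermodynamic context
#'
#' Bundles the Boltzmann constant with the absolute temperature used to
#' interconvert free energies, binding constants and selectivity
#' coefficients. The default temperature of 300 K matches the typical
#' simulation thermostat setting; experimental affinities measured near
#' room temperature can be converted with `temperature = 298.15`.
#'
#' @param temperature Absolute temperature in kelvin; must be positive.
#' @return An object of class `thermo_context` with fields `kB`
#'   (0.0019872041 kcal/(mol K)) and `temperature`.
#' @examples
#' ctx <- thermo_context()
#' ctx$kB * ctx$temperature  # kT in kcal/mol at 300 K
#' @export
thermo_context <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive number (kelvin)")
  structure(list(kB = .kB, temperature = as.double(temperature)),
            class = "thermo_context")
}

.kT <- function(ctx) ctx$kB * ctx$temperature
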