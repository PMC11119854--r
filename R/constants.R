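#' Physiological constants for oxygen-transport calculations
#'
#' Bundles the standard gas-exchange constants used throughout the package:
#' barometric and water-vapour pressures for the alveolar gas equation, the
#' respiratory quotient, haemoglobin oxygen-carrying capacity and the dissolved
#' oxygen solubility coefficient, plus the assumed arteriovenous oxygen content
#' difference that closes the shunt forward model.
#'
#' @param Pb Barometric pressure, mmHg.
#' @param PH2O Water vapour pressure at body temperature, mmHg.
#' @param RQ Respiratory quotient (CO2 produced / O2 consumed), unitless.
#' @param Hb_default Default haemoglobin concentration, g/dL, used when a
#'   sample does not carry its own value.
#' @param avDO2 Assumed arteriovenous oxygen content difference, mL O2/dL,
#'   used to close the mixed-venous side of the shunt equation.
#' @param hb_O2_capacity Oxygen-carrying capacity of haemoglobin, mL O2/g.
#' @param dissolved_O2_coeff Solubility of oxygen in plasma, mL O2/dL/mmHg.
#'
#' @return An object of class `physio_constants` (a named list).
#' @examples
#' physio_constants()
#' physio_constants(Hb_default = 10)
#' @export
physio_constants <- function(Pb = 760,
                             PH2O = 47,
                             RQ = 0.8,
                             Hb_default = 12,
                             avDO2 = 2.3,
                             hb_O2_capacity = 1.34,
                             dissolved_O2_coeff = 0.003) {
  const <- list(
    Pb = Pb, PH2O = PH2O, RQ = RQ, Hb_default = Hb_default,
    avDO2 = avDO2, hb_O2_capacity = hb_O2_capacity,
    dissolved_O2_coeff = dissolved_O2_coeff
  )
  bad <- names(const)[!vapply(const, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("physio_constants: all constants must be single positive numbers; bad: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (const$Pb <= const$PH2O) {
    stop("physio_constants: barometric pressure must exceed water vapour pressure", call. = FALSE)
  }
  structure(const, class = "physio_constants")
}

#' @export
print.physio_constants <- function(x, ...) {
  cat("<physio_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read physiological constants from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys are arguments of
#'   [physio_constants()]. Missing keys keep their defaults.
#' @return A `physio_constants` object.
#' @export
read_constants <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(physio_constants)))
  do.call(physio_constants, vals[keep])
}
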