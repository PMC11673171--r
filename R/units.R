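#' Convert a clinical concentration to molar
#'
#' Clinical chemistry reports bilirubin in mg/dL and albumin in g/dL, while the
#' binding equilibrium works in molar units. `clinical_to_molar()` and its
#' inverse `molar_to_clinical()` convert between the two given the species'
#' molar mass. The conversions are exact inverses (round-trip error below
#' 1e-12 relative).
#'
#' @param c Concentration in the clinical unit (`mg/dL` or `g/dL`).
#' @param mw Molar mass in g/mol. Must be positive.
#' @param unit Clinical unit of `c`, `"mg/dL"` (default, toxins) or `"g/dL"`
#'   (binders such as albumin).
#' @return Concentration in mol/L.
#' @examples
#' clinical_to_molar(15, 584.66)           # total bilirubin, mg/dL -> M
#' clinical_to_molar(2, 66430, "g/dL")     # BSA, g/dL -> M
#' @export
clinical_to_molar <- function(c, mw, unit = c("mg/dL", "g/dL")) {
  unit <- match.arg(unit)
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop("invalid parameter: molar mass must be positive", call. = FALSE)
  }
  if (any(c < 0, na.rm = TRUE)) {
    stop("invalid parameter: concentration must be non-negative", call. = FALSE)
  }
  # mg/dL -> 0.01 g/L ; g/dL -> 10 g/L
  g_per_L <- if (unit == "mg/dL") c * 1e-2 else c * 10
  g_per_L / mw
}

#' @rdname clinical_to_molar
#' @param m Concentration in mol/L.
#' @export
molar_to_clinical <- function(m, mw, unit = c("mg/dL", "g/dL")) {
  unit <- match.arg(unit)
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop("invalid parameter: molar mass must be positive", call. = FALSE)
  }
  g_per_L <- m * mw
  if (unit == "mg/dL") g_per_L / 1e-2 else g_per_L / 10
}

# Internal unit system: SI for geometry and pressure (m, Pa), mL/min for flows
# and conductances, mol/L for concentrations inside the binding math, minutes
# for session time. Clinical units appear only at I/O boundaries.

# m^3/s -> mL/min
.ML_MIN_PER_M3_S <- 6e7
# mL/min -> m^3/s
.M3_S_PER_ML_MIN <- 1 / 6e7
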