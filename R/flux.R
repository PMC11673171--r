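# Local transmembrane solute flux: Peclet number, its weighting function,
# the three-branch piecewise flux law, and the two conductance adjustment
# laws (flow dependence and area rescaling).

#' Transmembrane Peclet number
#'
#' Ratio of convective to diffusive transmembrane transport for the free
#' solute, `Pe = Jv (1 - sigma) L / kA`, with `Jv` the local ultrafiltration
#' flux per unit length, `L` the fiber length and `kA` the mass-transfer-area
#' coefficient. Inputs must be unit-coherent: with `Jv` in mL min^-1 m^-1,
#' `L` in m and `kA` in mL/min the result is dimensionless. The sign of `Pe`
#' follows the sign of `Jv` (positive during ultrafiltration, negative during
#' backfiltration).
#'
#' @param Jv Local ultrafiltration flux per unit length (mL min^-1 m^-1).
#' @param sigma Reflection coefficient.
#' @param L Fiber length (m).
#' @param kA Mass-transfer-area coefficient (mL/min); must be > 0. `kA = 0`
#'   is the pure-diffusion degenerate case and raises so the caller applies
#'   diffusive-branch semantics explicitly.
#' @return Dimensionless Peclet number.
#' @export
peclet <- function(Jv, sigma, L, kA) {
  if (any(kA <= 0)) {
    stop("pure-diffusion degenerate: kA must be > 0 (use the diffusive branch)",
         call. = FALSE)
  }
  Jv * (1 - sigma) * L / kA
}

#' Peclet weighting function
#'
#' `f(Pe) = 1/Pe - 1/(exp(Pe) - 1)`, the weight that partitions convective
#' transport between the two membrane faces. The singularity at `Pe = 0` is
#' removable; for `|Pe| < 1e-6` the series `1/2 - Pe/12` is used, avoiding
#' catastrophic cancellation. `f` is total on the reals, takes values in
#' (0, 1), and satisfies `f(Pe) + f(-Pe) = 1`.
#'
#' @param Pe Peclet number (vectorised, finite).
#' @return `f(Pe)`.
#' @examples
#' peclet_f(0)    # 1/2
#' peclet_f(1)    # 1 - 1/(e - 1)
#' @export
peclet_f <- function(Pe) {
  if (any(!is.finite(Pe))) stop("Pe must be finite", call. = FALSE)
  out <- numeric(length(Pe))
  small <- abs(Pe) < 1e-6
  out[small] <- 0.5 - Pe[small] / 12
  out[!small] <- 1 / Pe[!small] - 1 / expm1(Pe[!small])
  out
}

#' Critical ultrafiltration flux for branch selection
#'
#' Below this magnitude the local flux law switches to its purely diffusive
#' branch (the convective weighting is then numerically ill-conditioned and
#' physically negligible): `Jv_crit = min(Qb, Qd) * 1e-5` per mm of fiber.
#'
#' @param Qb,Qd Local flow rates, mL/min.
#' @return Threshold flux in mL min^-1 mm^-1.
#' @examples
#' jv_crit(150, 20)  # 2e-4
#' @export
jv_crit <- function(Qb, Qd) {
  if (any(Qb <= 0) || any(Qd <= 0)) {
    stop("invalid parameter: flows must be positive", call. = FALSE)
  }
  pmin(Qb, Qd) * 1e-5
}

#' Local transmembrane flux context
#'
#' Bundles the local state needed by [local_flux()].
#'
#' @param Jv_local Local ultrafiltration flux, mL min^-1 mm^-1.
#' @param Cs_b,Cs_d Free toxin concentrations on blood and dialysate side, M.
#' @param KfreeA_eff Effective (flow-adjusted) conductance, mL/min.
#' @param L Fiber length, m.
#' @param sigma Reflection coefficient.
#' @param Qb_local,Qd_local Local flow rates, mL/min.
#' @return An object of class `flux_context`.
#' @export
flux_context <- function(Jv_local, Cs_b, Cs_d, KfreeA_eff, L, sigma,
                         Qb_local, Qd_local) {
  ctx <- structure(list(Jv_local = Jv_local, Cs_b = Cs_b, Cs_d = Cs_d,
                        KfreeA_eff = KfreeA_eff, L = L, sigma = sigma,
                        Qb_local = Qb_local, Qd_local = Qd_local),
                   class = "flux_context")
  bad <- names(ctx)[!vapply(ctx, function(x) all(is.finite(x)), logical(1))]
  if (length(bad)) {
    stop("non-finite value in flux context field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (ctx$KfreeA_eff < 0 || ctx$Cs_b < 0 || ctx$Cs_d < 0) {
    stop("invalid flux context: conductance and concentrations must be >= 0",
         call. = FALSE)
  }
  ctx
}

#' Local axial derivative of the advected toxin amount
#'
#' Evaluates `d(Qb * Cstlb)/dz`, the local rate of change of the toxin amount
#' carried by the blood stream, under the piecewise convection-diffusion law.
#' In the middle branch (`|Jv| < Jv_crit`) transport is purely diffusive,
#' `-(KfreeA/L) (Cs_b - Cs_d)`. In the outer branches a convective term with
#' the Peclet weighting `f` and the advected free concentration of the
#' upstream side is added:
#' `[Jv (1-sigma) f - KfreeA/L] (Cs_b - Cs_d) - Jv (1-sigma) Cs_up`, with
#' `Cs_up = Cs_b` during ultrafiltration and `Cs_d` during backfiltration.
#' The outer branches converge to the middle branch as `Jv -> 0` (continuity
#' to first order), so the branch switch introduces no meaningful jump.
#'
#' @param ctx A [flux_context()].
#' @return `d(Qb Cstlb)/dz` in M mL min^-1 m^-1 (negative when toxin leaves
#'   the blood).
#' @export
local_flux <- function(ctx) {
  stopifnot(inherits(ctx, "flux_context"))
  # internal axial unit is the metre; Jv and Jv_crit arrive per mm
  Jv <- ctx$Jv_local * 1e3          # mL/min per m
  kA_L <- ctx$KfreeA_eff / ctx$L    # mL/min per m
  dC <- ctx$Cs_b - ctx$Cs_d
  Jc <- jv_crit(ctx$Qb_local, ctx$Qd_local) * 1e3
  if (abs(Jv) < Jc || ctx$sigma == 1) {
    return(-kA_L * dC)
  }
  if (ctx$KfreeA_eff == 0) {
    # pure-convection degenerate limit: |Pe| -> Inf, f -> 0 (Jv > 0) or 1
    f <- if (Jv > 0) 0 else 1
  } else {
    Pe <- peclet(Jv, ctx$sigma, ctx$L, ctx$KfreeA_eff)
    f <- peclet_f(Pe)
  }
  conv <- Jv * (1 - ctx$sigma)
  upstream <- if (Jv > 0) ctx$Cs_b else ctx$Cs_d
  (conv * f - kA_L) * dC - conv * upstream
}

#' Flow-adjusted mass-transfer-area coefficient
#'
#' The free-toxin conductance declines linearly as dialysate flow drops below
#' the 500 mL/min reference:
#' `KfreeA(Qd0) = KfreeA(500) * (1 + beta_Qd * (Qd0 - 500) / 300)`.
#' The adjustment uses the session's dialysate inlet flow, not the local
#' axial flow. A negative factor (possible only outside the physical
#' parameter region) is clamped to zero with a warning.
#'
#' @param tc A [transport_coefficients()].
#' @param Qd0 Dialysate inlet flow, mL/min (>= 0).
#' @return Conductance in mL/min.
#' @examples
#' tc <- transport_coefficients(769.23, beta_Qd = 0.45)
#' kfreeA_at_flow(tc, 500)  # reference value
#' kfreeA_at_flow(tc, 20)   # strongly reduced at low flow
#' @export
kfreeA_at_flow <- function(tc, Qd0) {
  stopifnot(inherits(tc, "transport_coefficients"))
  if (any(Qd0 < 0)) stop("invalid parameter: Qd0 must be >= 0", call. = FALSE)
  val <- tc$KfreeA_at_500 * (1 + tc$beta_Qd * (Qd0 - 500) / 300)
  if (any(val < 0)) {
    warning("flow-adjusted KfreeA is negative (unphysical parameter region); clamped to 0")
    val <- pmax(val, 0)
  }
  val
}

#' Rescale a conductance between dialyzers by membrane area
#'
#' Two dialyzers built from the same membrane are assumed to share the
#' intrinsic mass-transfer coefficient, so their conductances scale with
#' (nominal) membrane area: `kA_new = kA_old * area_new / area_old`.
#'
#' @param kA_old Conductance of the reference dialyzer, mL/min.
#' @param area_new,area_old Nominal membrane areas, m^2.
#' @return Conductance of the new dialyzer, mL/min.
#' @examples
#' rescale_kfreeA_by_area(2500, 0.4, 1.3)  # 769.23 mL/min
#' @export
rescale_kfreeA_by_area <- function(kA_old, area_new, area_old) {
  if (any(c(area_new, area_old) <= 0)) {
    stop("invalid parameter: areas must be positive", call. = FALSE)
  }
  kA_old * area_new / area_old
}
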