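# Axial hydraulics of the counter-current hollow-fiber module.
#
# Governing system (z from blood inlet, z = 0, to blood outlet, z = L;
# dialysate flows from z = L to z = 0, magnitudes positive):
#   dPb/dz = -a * Qb          a = 8 mu_b / (n pi ri^4)
#   dPd/dz = +b * Qd          b = 8 mu_d (Rm^2 + n ro^2) / (pi (Rm^2 - n ro^2)^3)
#   dQb/dz = dQd/dz = -kJ * (Pb - Pd),   kJ = 2 n pi ri Lp
# The dialysate-side resistance constant b is the adopted reading of the
# printed annulus expression; the grouping (Rm^2 + n ro^2) is the only
# dimensionally coherent one (Pa/m per m^3/s). It can be overridden via
# `resistance_dialysate`.
#
# With u = Pb - Pd and Qb - Qd constant, u'' = lambda^2 u with
# lambda = sqrt((a + b) kJ), so the system has a closed-form solution in
# hyperbolic functions. The gauge is Pd(0) = 0; the unknown blood-side
# pressure offset is fixed by the zero-net-ultrafiltration constraint
# (integral of u over [0, L] vanishes), which yields
#   u(z) = B [sinh(lambda z) - tanh(lambda L / 2) cosh(lambda z)]
#        = B sinh(lambda (z - L/2)) / cosh(lambda L / 2),
#   B = -(a Qb_in + b Qd_in) / lambda,
# i.e. the transmembrane pressure is antisymmetric about the midpoint:
# ultrafiltration in the proximal half, backfiltration in the distal half.

# sinh(x) - x without cancellation for small x
.sinhm <- function(x) {
  small <- abs(x) < 1e-3
  out <- x
  out[small] <- x[small]^3 / 6 * (1 + x[small]^2 / 20)
  out[!small] <- sinh(x[!small]) - x[!small]
  out
}

# cosh(x) - 1, stable
.coshm1 <- function(x) 2 * sinh(x / 2)^2

# Closed-form hydraulic field. Returns evaluator functions of z (metres):
# u (Pa), Qb, Qd (m^3/s), Pd (Pa), plus the constants used.
axial_hydraulics_field <- function(geom, fluids, Qb_in, Qd_in,
                                   resistance_dialysate = NULL) {
  n <- geom$n_fibers; ri <- geom$r_inner; ro <- geom$r_outer
  Rm <- geom$housing_radius; L <- geom$fiber_length
  annulus <- Rm^2 - n * ro^2
  if (annulus <= 0) {
    stop("invalid geometry: dialysate flow annulus is non-positive (Rm^2 <= n*ro^2)",
         call. = FALSE)
  }
  a <- 8 * fluids$mu_blood / (n * pi * ri^4)
  b <- if (is.null(resistance_dialysate)) {
    8 * fluids$mu_dialysate * (Rm^2 + n * ro^2) / (pi * annulus^3)
  } else {
    resistance_dialysate
  }
  if (b <= 0) stop("invalid geometry: dialysate resistance must be positive", call. = FALSE)
  kJ <- 2 * n * pi * ri * geom$Lp
  Qb0 <- Qb_in * .M3_S_PER_ML_MIN
  Qd0 <- Qd_in * .M3_S_PER_ML_MIN
  du0 <- -(a * Qb0 + b * Qd0)   # u'(0)

  if (kJ == 0) {
    u <- function(z) du0 * (z - L / 2)
    Qb <- function(z) rep_len(Qb0, length(z))
    Pd <- function(z) b * Qd0 * z
  } else {
    lambda <- sqrt((a + b) * kJ)
    B <- du0 / lambda
    A <- -B * tanh(lambda * L / 2)
    u <- function(z) A * cosh(lambda * z) + B * sinh(lambda * z)
    Qb <- function(z) {
      Qb0 - (kJ / lambda) * (A * sinh(lambda * z) + B * .coshm1(lambda * z))
    }
    Pd <- function(z) {
      b * (Qd0 * z - (kJ / lambda) *
             (A * .coshm1(lambda * z) / lambda +
              B * (.sinhm(lambda * z)) / lambda))
    }
  }
  Qd <- function(z) Qb(z) - (Qb0 - Qd0)
  list(u = u, Qb = Qb, Qd = Qd, Pd = Pd,
       a = a, b = b, kJ = kJ, L = L, Qb0 = Qb0, Qd0 = Qd0)
}

#' Solve the axial pressure/flow/ultrafiltration profile
#'
#' Computes the closed-form axial profile of blood and dialysate pressure,
#' flow rates and local ultrafiltration flux for a counter-current
#' hollow-fiber module under zero net ultrafiltration. The dialysate outlet
#' pressure is the gauge reference (`Pd(0) = 0`); the blood-side pressure
#' offset is fixed by requiring the ultrafiltration flux to integrate to zero
#' over the fiber length, reproducing bench operation where clamps balance
#' the circuit so no net fluid crosses the membrane. Local flux is still
#' nonzero: ultrafiltration (blood to dialysate) near the blood inlet,
#' backfiltration near the blood outlet.
#'
#' @param geom A [dialyzer_geometry()].
#' @param fluids A [fluid_properties()].
#' @param Qb_in,Qd_in Inlet blood and dialysate flow rates, mL/min.
#' @param n_z Number of grid points (default 201).
#' @param resistance_dialysate Optional override of the dialysate-side
#'   hydraulic resistance constant (Pa m^-1 per m^3 s^-1); by default it is
#'   computed from the shell/fiber-bundle geometry.
#' @return A tibble of class `axial_profile` with columns `z` (m), `Pb` (Pa),
#'   `Pd` (Pa), `Qb` (mL/min), `Qd` (mL/min), `Jv` (mL min^-1 mm^-1; positive
#'   means ultrafiltration from blood to dialysate). Attributes carry the
#'   hydraulic constants.
#' @examples
#' f3 <- dialyzer_geometry(2304, 100, 140, 20, 11, 0.4, 8.61e-11)
#' prof <- solve_axial_hydraulics(f3, fluid_properties(), 150, 150)
#' summary(prof$Jv)
#' @export
solve_axial_hydraulics <- function(geom, fluids, Qb_in, Qd_in, n_z = 201,
                                   resistance_dialysate = NULL) {
  validate_geometry(geom)
  if (Qb_in <= 0 || Qd_in <= 0) {
    stop("invalid parameter: flows must be positive", call. = FALSE)
  }
  fld <- axial_hydraulics_field(geom, fluids, Qb_in, Qd_in, resistance_dialysate)
  z <- seq(0, geom$fiber_length, length.out = n_z)
  uz <- fld$u(z)
  out <- tibble::tibble(
    z = z,
    Pb = fld$Pd(z) + uz,
    Pd = fld$Pd(z),
    Qb = fld$Qb(z) * .ML_MIN_PER_M3_S,
    Qd = fld$Qd(z) * .ML_MIN_PER_M3_S,
    # kJ * u is volume flux per metre of axial length (m^3 s^-1 m^-1);
    # convert to mL/min per mm
    Jv = fld$kJ * uz * .ML_MIN_PER_M3_S * 1e-3
  )
  structure(out,
            class = c("axial_profile", class(out)),
            hydraulics = fld[c("a", "b", "kJ", "L", "Qb0", "Qd0")])
}

#' Plot an axial profile
#'
#' Pressure, flow and local ultrafiltration flux against axial position.
#'
#' @param object An `axial_profile` from [solve_axial_hydraulics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.axial_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("Pb", "Pd", "Qb", "Qd", "Jv"),
    names_to = "variable", values_to = "value"
  )
  long$panel <- dplyr::case_when(
    long$variable %in% c("Pb", "Pd") ~ "pressure (Pa)",
    long$variable %in% c("Qb", "Qd") ~ "flow (mL/min)",
    TRUE ~ "Jv (mL/min/mm)"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "z (m)", y = NULL, colour = NULL)
}

#' Membrane area of a fiber bundle from lumen geometry
#'
#' Inner (lumen) membrane area `2 pi ri L n`. For commercial dialyzers this
#' generally differs from the data-sheet nominal area; both are carried by
#' [dialyzer_geometry()] and the nominal area is the one used for conductance
#' rescaling.
#'
#' @param n Number of fibers.
#' @param ri Inner fiber radius, m.
#' @param L Fiber length, m.
#' @return Area in m^2.
#' @examples
#' fiber_lumen_area(10, 100e-6, 0.15) * 1e4  # cm^2, bench mini-module
#' @export
fiber_lumen_area <- function(n, ri, L) {
  if (any(c(n, ri, L) <= 0)) {
    stop("invalid parameter: n, ri and L must be positive", call. = FALSE)
  }
  2 * pi * ri * L * n
}

#' Bundle an ultrafiltration bench measurement
#'
#' @param dV_ml Ultrafiltrate volume collected, mL.
#' @param dt_min Collection time, min.
#' @param Pb_in,Pb_out Blood-side inlet/outlet pressures, Pa.
#' @param Pd_in,Pd_out Dialysate-side pressures, Pa (default 0; for a module
#'   submerged in an open bath they are negligible).
#' @param area_m2 Membrane area of the module, m^2.
#' @return An object of class `permeability_measurement`.
#' @export
permeability_measurement <- function(dV_ml, dt_min, Pb_in, Pb_out,
                                     Pd_in = 0, Pd_out = 0, area_m2) {
  if (dt_min <= 0) stop("invalid measurement: dt must be positive", call. = FALSE)
  if (area_m2 <= 0) stop("invalid measurement: area must be positive", call. = FALSE)
  structure(list(dV_ml = dV_ml, dt_min = dt_min, Pb_in = Pb_in,
                 Pb_out = Pb_out, Pd_in = Pd_in, Pd_out = Pd_out,
                 area_m2 = area_m2),
            class = "permeability_measurement")
}

#' Hydraulic permeability from an ultrafiltration measurement
#'
#' `Lp = (dV/dt) / (P * A)` where `P` is the transmembrane driving pressure,
#' the difference of the mean blood-side and mean dialysate-side pressures:
#' `P = (Pb_in + Pb_out)/2 - (Pd_in + Pd_out)/2`.
#'
#' @param m A [permeability_measurement()].
#' @return Hydraulic permeability in m s^-1 Pa^-1.
#' @examples
#' m <- permeability_measurement(dV_ml = 0.05, dt_min = 10,
#'                               Pb_in = 10200, Pb_out = 9800,
#'                               area_m2 = 9.42e-4)
#' hydraulic_permeability(m)
#' @export
hydraulic_permeability <- function(m) {
  stopifnot(inherits(m, "permeability_measurement"))
  P <- (m$Pb_in + m$Pb_out) / 2 - (m$Pd_in + m$Pd_out) / 2
  if (P <= 0) {
    stop("degenerate pressure: no transmembrane driving force (P <= 0)",
         call. = FALSE)
  }
  (m$dV_ml * 1e-6 / (m$dt_min * 60)) / (P * m$area_m2)
}

#' Export an axial profile to CSV
#'
#' @param profile An `axial_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_axial_profile <- function(profile, path) {
  stopifnot(inherits(profile, "axial_profile"))
  utils::write.csv(tibble::as_tibble(profile), path, row.names = FALSE)
  invisible(path)
}
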