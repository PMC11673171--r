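#' Dialyzer geometry
#'
#' Validated container for hollow-fiber dialyzer geometry and membrane
#' properties. Lengths are given in the units conventionally quoted on data
#' sheets (fiber radii in micrometres, fiber length in centimetres, housing
#' radius in millimetres, area in square metres) and stored internally in SI.
#'
#' @param n_fibers Number of hollow fibers (>= 1).
#' @param r_inner_um Fiber inner radius, micrometres.
#' @param r_outer_um Fiber outer radius, micrometres (> `r_inner_um`).
#' @param fiber_length_cm Fiber length, centimetres.
#' @param housing_radius_mm Inner radius of the dialyzer shell, millimetres.
#' @param area_nominal_m2 Nominal membrane area from the data sheet, m^2. Used
#'   only for conductance rescaling between dialyzers
#'   ([rescale_kfreeA_by_area()]); geometric areas are computed from the fiber
#'   dimensions where needed ([fiber_lumen_area()]). The two generally
#'   disagree; both are carried.
#' @param Lp Membrane hydraulic permeability, m s^-1 Pa^-1.
#' @param sigma Solute reflection coefficient, in `[0, 1]`. 0 means the solute
#'   is freely convected.
#' @return An object of class `dialyzer_geometry`: a list with fields
#'   `n_fibers`, `r_inner` (m), `r_outer` (m), `fiber_length` (m),
#'   `housing_radius` (m), `area_nominal` (m^2), `Lp`, `sigma`.
#' @examples
#' f3 <- dialyzer_geometry(2304, 100, 140, 20, 11, 0.4, 8.61e-11, 0)
#' fiber_lumen_area(f3$n_fibers, f3$r_inner, f3$fiber_length)
#' @export
dialyzer_geometry <- function(n_fibers, r_inner_um, r_outer_um, fiber_length_cm,
                              housing_radius_mm, area_nominal_m2, Lp,
                              sigma = 0) {
  g <- structure(list(
    n_fibers = as.numeric(n_fibers),
    r_inner = r_inner_um * 1e-6,
    r_outer = r_outer_um * 1e-6,
    fiber_length = fiber_length_cm * 1e-2,
    housing_radius = housing_radius_mm * 1e-3,
    area_nominal = area_nominal_m2,
    Lp = Lp,
    sigma = sigma
  ), class = "dialyzer_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stop_invalid <- function(msg) stop("invalid geometry: ", msg, call. = FALSE)
  num <- vapply(g, is.numeric, logical(1))
  if (!all(num)) stop_invalid("all fields must be numeric")
  if (any(!vapply(g, is.finite, logical(1)))) stop_invalid("all fields must be finite")
  if (g$n_fibers < 1) stop_invalid("n_fibers must be >= 1")
  with(g, {
    if (r_inner <= 0 || r_outer <= 0 || fiber_length <= 0 ||
        housing_radius <= 0 || area_nominal <= 0) {
      stop_invalid("all lengths and areas must be positive")
    }
    if (r_inner >= r_outer) stop_invalid("r_inner must be < r_outer")
    if (sigma < 0 || sigma > 1) stop_invalid("sigma must lie in [0, 1]")
    if (Lp < 0) stop_invalid("Lp must be >= 0")
    if (n_fibers * r_outer^2 >= housing_radius^2) {
      stop_invalid("fiber bundle does not fit in the housing (n*r_outer^2 >= housing_radius^2)")
    }
  })
  invisible(g)
}

#' Fluid dynamic viscosities
#'
#' The study's blood analog is albumin dissolved in dialysate, so both sides
#' default to the viscosity of an aqueous solution at 37 degrees C
#' (6.9e-4 Pa s). Override for plasma or whole blood.
#'
#' @param mu_blood,mu_dialysate Dynamic viscosities, Pa s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(mu_blood = 6.9e-4, mu_dialysate = 6.9e-4) {
  if (!is.numeric(mu_blood) || !is.numeric(mu_dialysate) ||
      mu_blood <= 0 || mu_dialysate <= 0) {
    stop("invalid fluid properties: viscosities must be positive", call. = FALSE)
  }
  structure(list(mu_blood = mu_blood, mu_dialysate = mu_dialysate),
            class = "fluid_properties")
}

#' Binder-toxin solute system
#'
#' Single-site equilibrium binding system. Defaults are bilirubin
#' (584.66 g/mol) bound by bovine serum albumin (66430 g/mol).
#'
#' @param KB Primary-site binding constant, 1/M.
#' @param mw_toxin,mw_binder Molar masses, g/mol.
#' @return An object of class `solute_system`.
#' @export
solute_system <- function(KB, mw_toxin = 584.66, mw_binder = 66430) {
  if (!is.numeric(KB) || KB <= 0) {
    stop("invalid solute system: KB must be positive", call. = FALSE)
  }
  if (mw_toxin <= 0 || mw_binder <= 0) {
    stop("invalid solute system: molar masses must be positive", call. = FALSE)
  }
  structure(list(KB = KB, mw_toxin = mw_toxin, mw_binder = mw_binder),
            class = "solute_system")
}

#' Operating point of a dialysis session
#'
#' Flows, reservoir volumes, starting compositions and duration, in clinical
#' units.
#'
#' @param Qb_in,Qd_in Blood and dialysate flow rates, mL/min.
#' @param Vb,Vd Blood and dialysate reservoir volumes, mL.
#' @param Cb_toxin0 Starting total toxin in the blood reservoir, mg/dL.
#' @param Cb_albumin,Cd_albumin Albumin on each side, g/dL.
#' @param Cd_toxin0 Starting total toxin in the dialysate reservoir, mg/dL.
#' @param duration_h Session duration, hours.
#' @return An object of class `operating_point`.
#' @export
operating_point <- function(Qb_in, Qd_in, Vb, Vd, Cb_toxin0, Cb_albumin,
                            Cd_albumin, Cd_toxin0 = 0, duration_h) {
  op <- structure(list(
    Qb_in = Qb_in, Qd_in = Qd_in, Vb = Vb, Vd = Vd,
    Cb_toxin0 = Cb_toxin0, Cb_albumin = Cb_albumin,
    Cd_albumin = Cd_albumin, Cd_toxin0 = Cd_toxin0,
    duration_h = duration_h
  ), class = "operating_point")
  if (any(!vapply(op, is.numeric, logical(1)))) {
    stop("invalid operating point: all fields must be numeric", call. = FALSE)
  }
  if (op$Qb_in <= 0 || op$Qd_in <= 0) {
    stop("invalid operating point: flows must be positive", call. = FALSE)
  }
  if (op$Vb <= 0 || op$Vd <= 0) {
    stop("invalid operating point: volumes must be positive", call. = FALSE)
  }
  if (op$Cb_toxin0 < 0 || op$Cb_albumin < 0 || op$Cd_albumin < 0 ||
      op$Cd_toxin0 < 0) {
    stop("invalid operating point: concentrations must be non-negative", call. = FALSE)
  }
  if (op$duration_h <= 0) {
    stop("invalid operating point: duration must be positive", call. = FALSE)
  }
  op
}

#' Membrane transport coefficients for the free toxin
#'
#' The free-toxin mass-transfer-area coefficient is referenced at a dialysate
#' flow of 500 mL/min and adjusted linearly with dialysate flow (the
#' adjustment scale is 300 mL/min); `beta_Qd` is the fractional change per
#' 300 mL/min. `beta_Qd = 0.6` is the physical upper bound: it drives the
#' coefficient to zero at zero dialysate flow.
#'
#' @param KfreeA_at_500 Conductance at the 500 mL/min reference flow, mL/min.
#' @param beta_Qd Fractional change per 300 mL/min change in dialysate flow,
#'   in `[0, 0.6]`.
#' @return An object of class `transport_coefficients`.
#' @seealso [kfreeA_at_flow()], [rescale_kfreeA_by_area()]
#' @export
transport_coefficients <- function(KfreeA_at_500, beta_Qd = 0.05544) {
  if (!is.numeric(KfreeA_at_500) || KfreeA_at_500 <= 0) {
    stop("invalid transport coefficients: KfreeA_at_500 must be positive", call. = FALSE)
  }
  if (!is.numeric(beta_Qd) || beta_Qd < 0 || beta_Qd > 0.6) {
    stop("invalid transport coefficients: beta_Qd must lie in [0, 0.6]", call. = FALSE)
  }
  structure(list(KfreeA_at_500 = KfreeA_at_500, beta_Qd = beta_Qd),
            class = "transport_coefficients")
}

#' Assemble a full dialysis setup
#'
#' @param geometry A [dialyzer_geometry()].
#' @param fluids A [fluid_properties()].
#' @param solute A [solute_system()].
#' @param operating An [operating_point()].
#' @param transport A [transport_coefficients()].
#' @return An object of class `dialysis_setup` bundling the five components.
#' @export
dialysis_setup <- function(geometry, fluids, solute, operating, transport) {
  stopifnot(inherits(geometry, "dialyzer_geometry"),
            inherits(fluids, "fluid_properties"),
            inherits(solute, "solute_system"),
            inherits(operating, "operating_point"),
            inherits(transport, "transport_coefficients"))
  structure(list(geometry = geometry, fluids = fluids, solute = solute,
                 operating = operating, transport = transport),
            class = "dialysis_setup")
}

#' @export
print.dialysis_setup <- function(x, ...) {
  g <- x$geometry; o <- x$operating
  cat("<dialysis_setup>\n")
  cat(sprintf("  dialyzer: %d fibers, L = %.3g cm, nominal area %.3g m^2\n",
              as.integer(g$n_fibers), g$fiber_length * 100, g$area_nominal))
  cat(sprintf("  flows: Qb = %g, Qd = %g mL/min; reservoirs %g / %g mL\n",
              o$Qb_in, o$Qd_in, o$Vb, o$Vd))
  cat(sprintf("  toxin: %g mg/dL blood start; albumin %g / %g g/dL; %g h\n",
              o$Cb_toxin0, o$Cb_albumin, o$Cd_albumin, o$duration_h))
  cat(sprintf("  KfreeA(500) = %g mL/min, beta_Qd = %g, KB = %.3g 1/M\n",
              x$transport$KfreeA_at_500, x$transport$beta_Qd, x$solute$KB))
  invisible(x)
}

.setup_schema <- list(
  dialyzer = c("n_fibers", "r_inner_um", "r_outer_um", "fiber_length_cm",
               "housing_radius_mm", "area_nominal_m2", "Lp_m_per_s_Pa", "sigma"),
  fluids = c("mu_blood_Pa_s", "mu_dialysate_Pa_s"),
  solute = c("KB_per_M", "mw_toxin_g_mol", "mw_binder_g_mol"),
  operating = c("Qb_ml_min", "Qd_ml_min", "Vb_ml", "Vd_ml",
                "Cb_toxin0_mg_dl", "Cb_albumin_g_dl", "Cd_albumin_g_dl",
                "Cd_toxin0_mg_dl", "duration_h"),
  transport = c("KfreeA_at_500_ml_min", "beta_Qd")
)

# fields with defaults; everything else is required
.setup_optional <- list(
  dialyzer = c("sigma"),
  fluids = c("mu_blood_Pa_s", "mu_dialysate_Pa_s"),
  solute = c("mw_toxin_g_mol", "mw_binder_g_mol"),
  operating = c("Cd_toxin0_mg_dl"),
  transport = c("beta_Qd")
)

#' Load a dialysis setup from a YAML configuration file
#'
#' The file has five blocks (`dialyzer`, `fluids`, `solute`, `operating`,
#' `transport`) with explicitly unit-annotated keys; see the fixtures shipped
#' under `inst/extdata` (`f6hps.yaml`, `f3_qd150.yaml`, `f3_qd20.yaml`,
#' `f3_qd800.yaml`, `f3_qd2.yaml`) which encode the five bench setups.
#' Unknown keys are rejected; a missing required key raises a schema error
#' naming the field; values violating a type invariant raise a validation
#' error.
#'
#' @param path Path to a YAML file.
#' @return A [dialysis_setup()].
#' @examples
#' path <- system.file("extdata", "f3_qd20.yaml", package = "albudial")
#' load_setup(path)
#' @export
load_setup <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)

  extra_blocks <- setdiff(names(raw), names(.setup_schema))
  if (length(extra_blocks)) {
    stop("schema error: unknown block(s): ", paste(extra_blocks, collapse = ", "),
         call. = FALSE)
  }
  for (blk in names(.setup_schema)) {
    if (is.null(raw[[blk]])) {
      stop("schema error: missing block '", blk, "'", call. = FALSE)
    }
    unknown <- setdiff(names(raw[[blk]]), .setup_schema[[blk]])
    if (length(unknown)) {
      stop("schema error: unknown key(s) in '", blk, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    required <- setdiff(.setup_schema[[blk]], .setup_optional[[blk]])
    missing <- setdiff(required, names(raw[[blk]]))
    if (length(missing)) {
      stop("schema error: missing required field '", blk, ".", missing[1], "'",
           call. = FALSE)
    }
  }

  d <- raw$dialyzer; fl <- raw$fluids; s <- raw$solute
  o <- raw$operating; tr <- raw$transport
  grab <- function(x, key, default = NULL) if (is.null(x[[key]])) default else x[[key]]

  geometry <- dialyzer_geometry(
    n_fibers = d$n_fibers, r_inner_um = d$r_inner_um, r_outer_um = d$r_outer_um,
    fiber_length_cm = d$fiber_length_cm, housing_radius_mm = d$housing_radius_mm,
    area_nominal_m2 = d$area_nominal_m2, Lp = d$Lp_m_per_s_Pa,
    sigma = grab(d, "sigma", 0)
  )
  fluids <- fluid_properties(
    mu_blood = grab(fl, "mu_blood_Pa_s", 6.9e-4),
    mu_dialysate = grab(fl, "mu_dialysate_Pa_s", 6.9e-4)
  )
  solute <- solute_system(
    KB = s$KB_per_M,
    mw_toxin = grab(s, "mw_toxin_g_mol", 584.66),
    mw_binder = grab(s, "mw_binder_g_mol", 66430)
  )
  operating <- operating_point(
    Qb_in = o$Qb_ml_min, Qd_in = o$Qd_ml_min, Vb = o$Vb_ml, Vd = o$Vd_ml,
    Cb_toxin0 = o$Cb_toxin0_mg_dl, Cb_albumin = o$Cb_albumin_g_dl,
    Cd_albumin = o$Cd_albumin_g_dl,
    Cd_toxin0 = grab(o, "Cd_toxin0_mg_dl", 0),
    duration_h = o$duration_h
  )
  transport <- transport_coefficients(
    KfreeA_at_500 = tr$KfreeA_at_500_ml_min,
    beta_Qd = grab(tr, "beta_Qd", 0.05544)
  )
  dialysis_setup(geometry, fluids, solute, operating, transport)
}
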