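# Fixtures and independent oracles shared across the test files.

fixture_setup <- function(name) {
  load_setup(system.file("extdata", paste0(name, ".yaml"), package = "albudial"))
}

fixture_names <- c("f6hps", "f3_qd150", "f3_qd20", "f3_qd800", "f3_qd2")

# A small, fast condition used where the physical scale of the bench setups
# is not the point: F3 geometry, short session, small reservoirs.
quick_setup <- function(Qd = 150, KB = 5e6, kA500 = 769.23, beta = 0.45,
                        duration_h = 1, Vb = 100, Vd = 100,
                        Cb0 = 15, Cb_alb = 2, Cd_alb = 2) {
  dialysis_setup(
    dialyzer_geometry(2304, 100, 140, 20, 11, 0.4, 8.61e-11, 0),
    fluid_properties(),
    solute_system(KB),
    operating_point(Qb_in = 150, Qd_in = Qd, Vb = Vb, Vd = Vd,
                    Cb_toxin0 = Cb0, Cb_albumin = Cb_alb,
                    Cd_albumin = Cd_alb, duration_h = duration_h),
    transport_coefficients(kA500, beta)
  )
}

# --- independent bisection oracle for the binding equilibrium ---------------
# Solves KB = (Ct - Cs) / (Cs (Ca - Ct + Cs)) for Cs by bracketed bisection,
# never touching the closed-form quadratic.
bisect_free_toxin <- function(c_total, c_binder, KB) {
  if (c_total == 0) return(0)
  g <- function(cs) (c_total - cs) - KB * cs * (c_binder - c_total + cs)
  lo <- 0; hi <- c_total
  # 200 unconditional halvings: the bracket collapses to adjacent doubles
  # even when the root is many orders below c_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# --- independent dense solution of the single-pass BVP ----------------------
# Classical fixed-step RK4 on a grid 10x finer than the production solver's
# 1 mm cap, evaluating the hydraulic field analytically at arbitrary z and
# the flux law through the R-level module surface; the root in xy0 is found
# by Brent's method. Shares no code path with the compiled shooting solver.
oracle_pass_delta <- function(p, xy0, n_steps = 2000) {
  op <- p$setup$operating
  L <- p$setup$geometry$fiber_length
  Cd_out <- p$Cd_in - xy0 / op$Qd_in
  rhs <- function(z, chi) {
    Qb <- p$field$Qb(z) * 6e7
    Qd <- p$field$Qd(z) * 6e7
    Jv_mm <- p$field$kJ * p$field$u(z) * 6e7 * 1e-3
    Cstlb <- (op$Qb_in * p$Cb_in + chi) / Qb
    Cstld <- (chi + Cd_out * op$Qd_in) / Qd
    Csb <- free_toxin(max(Cstlb, 0), p$Catlb_in * op$Qb_in / Qb,
                      p$setup$solute$KB)
    Csd <- free_toxin(max(Cstld, 0), p$Catld_in * op$Qd_in / Qd,
                      p$setup$solute$KB)
    local_flux(flux_context(Jv_mm, Csb, Csd, p$KfreeA_eff, L, p$sigma, Qb, Qd))
  }
  h <- -L / n_steps
  z <- L
  chi <- xy0
  for (i in seq_len(n_steps)) {
    k1 <- rhs(z, chi)
    k2 <- rhs(z + h / 2, chi + h * k1 / 2)
    k3 <- rhs(z + h / 2, chi + h * k2 / 2)
    k4 <- rhs(z + h, chi + h * k3)
    chi <- chi + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    z <- z + h
  }
  chi
}

oracle_pass_xy0 <- function(p, n_steps = 2000) {
  amount_in <- p$setup$operating$Qb_in * p$Cb_in
  stats::uniroot(function(x) oracle_pass_delta(p, x, n_steps),
                 interval = c(-amount_in, 0),
                 tol = 1e-12 * amount_in)$root
}

# --- closed-form equilibrium of the two-reservoir system --------------------
# At t -> infinity the free toxin concentrations on the two sides equalise;
# with total mass conserved this determines the final totals. Solved by
# Brent's method on the free-concentration mismatch.
equilibrium_final_Cb <- function(setup) {
  op <- setup$operating; sol <- setup$solute
  Cb0 <- clinical_to_molar(op$Cb_toxin0, sol$mw_toxin, "mg/dL")
  Cd0 <- clinical_to_molar(op$Cd_toxin0, sol$mw_toxin, "mg/dL")
  Ab <- clinical_to_molar(op$Cb_albumin, sol$mw_binder, "g/dL")
  Ad <- clinical_to_molar(op$Cd_albumin, sol$mw_binder, "g/dL")
  total <- op$Vb * Cb0 + op$Vd * Cd0
  mismatch <- function(Cb) {
    Cd <- (total - op$Vb * Cb) / op$Vd
    free_toxin(Cb, Ab, sol$KB) - free_toxin(Cd, Ad, sol$KB)
  }
  Cb_eq <- stats::uniroot(mismatch, interval = c(1e-12 * Cb0, Cb0),
                          tol = 1e-14 * Cb0)$root
  molar_to_clinical(Cb_eq, sol$mw_toxin, "mg/dL")
}
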