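# independent dense numerical integration of the four pressure/flow ODEs,
# with the blood-side pressure offset found by root-finding on the
# zero-net-ultrafiltration condition; shares nothing with the closed form
dense_hydraulics <- function(geom, fluids, Qb_in, Qd_in, z_out) {
  a <- 8 * fluids$mu_blood / (geom$n_fibers * pi * geom$r_inner^4)
  b <- 8 * fluids$mu_dialysate *
    (geom$housing_radius^2 + geom$n_fibers * geom$r_outer^2) /
    (pi * (geom$housing_radius^2 - geom$n_fibers * geom$r_outer^2)^3)
  kJ <- 2 * geom$n_fibers * pi * geom$r_inner * geom$Lp
  Qb0 <- Qb_in / 6e7; Qd0 <- Qd_in / 6e7
  rhs <- function(z, y, parms) {
    list(c(-a * y[3], b * y[4], -kJ * (y[1] - y[2]), -kJ * (y[1] - y[2])))
  }
  run <- function(Pb0) {
    deSolve::lsoda(c(Pb0, 0, Qb0, Qd0), z_out, rhs, NULL,
                   rtol = 1e-12, atol = 1e-16)
  }
  net_uf <- function(Pb0) {
    out <- run(Pb0)
    out[nrow(out), 4] - Qb0
  }
  span <- a * Qb0 * geom$fiber_length * 10 + 1
  Pb0 <- stats::uniroot(net_uf, c(-span, span), tol = 1e-14)$root
  out <- run(Pb0)
  list(Pb = out[, 2], Pd = out[, 3], Qb = out[, 4] * 6e7, Qd = out[, 5] * 6e7,
       Jv = kJ * (out[, 2] - out[, 3]) * 6e7 * 1e-3)
}

test_that("closed-form profile matches a dense numerical integration", {
  s <- fixture_setup("f3_qd150")
  prof <- solve_axial_hydraulics(s$geometry, s$fluids, 150, 150, n_z = 101)
  ref <- dense_hydraulics(s$geometry, s$fluids, 150, 150, prof$z)
  scale_P <- max(abs(ref$Pb))
  expect_lt(max(abs(prof$Pb - ref$Pb)) / scale_P, 1e-6)
  expect_lt(max(abs(prof$Pd - ref$Pd)) / scale_P, 1e-6)
  expect_lt(max(abs(prof$Qb - ref$Qb)) / 150, 1e-6)
  expect_lt(max(abs(prof$Qd - ref$Qd)) / 150, 1e-6)
  expect_lt(max(abs(prof$Jv - ref$Jv)) / max(abs(ref$Jv)), 1e-6)
})

test_that("zero-permeability limit decouples to plain Poiseuille flow", {
  g <- dialyzer_geometry(2304, 100, 140, 20, 11, 0.4, Lp = 0)
  fl <- fluid_properties()
  prof <- solve_axial_hydraulics(g, fl, 150, 150, n_z = 51)
  expect_true(all(prof$Jv == 0))
  expect_equal(prof$Qb, rep(150, 51), tolerance = 1e-12)
  expect_equal(prof$Qd, rep(150, 51), tolerance = 1e-12)
  slope <- diff(prof$Pb) / diff(prof$z)
  expect_equal(slope,
               rep(-8 * fl$mu_blood * (150 / 6e7) / (2304 * pi * 1e-16),
                   50), tolerance = 1e-10)
})

test_that("net ultrafiltration vanishes and flux obeys the local pressure law", {
  for (flows in list(c(150, 150), c(180, 90), c(150, 2))) {
    s <- fixture_setup("f3_qd150")
    prof <- solve_axial_hydraulics(s$geometry, s$fluids, flows[1], flows[2],
                                   n_z = 401)
    # trapezoidal integral of Jv over z (Jv per mm -> per m) vs inlet flow
    dz <- diff(prof$z)
    net <- sum((prof$Jv[-1] + prof$Jv[-length(prof$Jv)]) / 2 * dz * 1e3)
    expect_lt(abs(net) / flows[1], 1e-8)
    # pointwise Jv = 2 n pi ri Lp (Pb - Pd), unit-converted
    g <- s$geometry
    jv_law <- 2 * g$n_fibers * pi * g$r_inner * g$Lp * (prof$Pb - prof$Pd) *
      6e7 * 1e-3
    expect_equal(prof$Jv, jv_law, tolerance = 1e-10)
    # flow endpoints return to their inlet values
    expect_equal(prof$Qb[1], prof$Qb[length(prof$Qb)], tolerance = 1e-8)
    expect_equal(prof$Qd[1], prof$Qd[length(prof$Qd)], tolerance = 1e-8)
  }
})

test_that("pressures are monotone and transmembrane pressure is antisymmetric", {
  s <- fixture_setup("f6hps")
  prof <- solve_axial_hydraulics(s$geometry, s$fluids, 180, 90, n_z = 201)
  expect_true(all(diff(prof$Pb) < 0))
  expect_true(all(diff(prof$Pd) > 0))  # dialysate flows toward z = 0
  u <- prof$Pb - prof$Pd
  expect_equal(u, -rev(u), tolerance = 1e-9)
  # ultrafiltration proximal, backfiltration distal
  expect_gt(prof$Jv[1], 0)
  expect_lt(prof$Jv[length(prof$Jv)], 0)
})

test_that("profile is grid-converged (closed form is exact on any grid)", {
  s <- fixture_setup("f3_qd20")
  p1 <- solve_axial_hydraulics(s$geometry, s$fluids, 150, 20, n_z = 101)
  p2 <- solve_axial_hydraulics(s$geometry, s$fluids, 150, 20, n_z = 201)
  expect_equal(p1$Pb, p2$Pb[seq(1, 201, 2)], tolerance = 1e-12)
  expect_equal(p1$Jv, p2$Jv[seq(1, 201, 2)], tolerance = 1e-12)
  # CSV export carries the full profile schema
  path <- tempfile(fileext = ".csv")
  write_axial_profile(p1, path)
  back <- utils::read.csv(path)
  expect_named(back, c("z", "Pb", "Pd", "Qb", "Qd", "Jv"))
  expect_equal(back$Jv, p1$Jv, tolerance = 1e-12)
})

test_that("hydraulic permeability inverts the ultrafiltration law", {
  # forward-inverse consistency on a synthetic mini-module measurement
  area <- fiber_lumen_area(10, 100e-6, 0.15)
  Lp_true <- 8.61e-11
  P <- 10e3
  dV_dt_ml_min <- Lp_true * P * area * 6e7
  m <- permeability_measurement(dV_ml = dV_dt_ml_min * 10, dt_min = 10,
                                Pb_in = P, Pb_out = P, area_m2 = area)
  expect_equal(hydraulic_permeability(m), Lp_true, tolerance = 1e-12)

  # doubling the driving pressure at fixed flux halves Lp
  m2 <- permeability_measurement(dV_ml = m$dV_ml, dt_min = 10,
                                 Pb_in = 2 * P, Pb_out = 2 * P, area_m2 = area)
  expect_equal(hydraulic_permeability(m2), Lp_true / 2, tolerance = 1e-12)

  # the mean-pressure formula uses both sides
  m3 <- permeability_measurement(dV_ml = m$dV_ml, dt_min = 10,
                                 Pb_in = 1.5 * P, Pb_out = 0.5 * P,
                                 Pd_in = 0, Pd_out = 0, area_m2 = area)
  expect_equal(hydraulic_permeability(m3), Lp_true, tolerance = 1e-12)

  expect_error(
    hydraulic_permeability(permeability_measurement(1, 1, 0, 0, 0, 0, area)),
    "degenerate pressure")
})

test_that("lumen area matches the bench mini-module and exposes the nominal-area gap", {
  # 9.42 cm^2 to three significant figures
  expect_equal(round(fiber_lumen_area(10, 100e-6, 0.15) * 1e4, 2), 9.42)
  expect_equal(fiber_lumen_area(1, 1 / (2 * pi), 1), 1, tolerance = 1e-14)
  # F3 geometric lumen area is ~0.29 m^2, well below the 0.4 m^2 data sheet
  a_f3 <- fiber_lumen_area(2304, 100e-6, 0.20)
  expect_equal(a_f3, 0.2895, tolerance = 1e-3)
  expect_lt(a_f3, 0.4)
  expect_error(fiber_lumen_area(0, 1e-4, 0.2), "positive")
})
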