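no_transport_setup <- function() {
  dialysis_setup(
    dialyzer_geometry(2304, 100, 140, 20, 11, 0.4, Lp = 0),
    fluid_properties(),
    solute_system(5e6),
    operating_point(150, 150, 200, 200, 18.81, 1.90, 1.94, 0, 5),
    transport_coefficients(769.23, 0)
  )
}

test_that("shoot_once: no-transport fixed point and necessity of removal", {
  s <- no_transport_setup()
  p0 <- single_pass_problem(s, KfreeA_eff = 0)
  r <- shoot_once(p0, 0)
  expect_true(r$stable)
  expect_equal(r$delta, 0, tolerance = 1e-14)

  # with transport on, zero removal is inconsistent with the gradient
  s2 <- fixture_setup("f3_qd150")
  p2 <- single_pass_problem(s2)
  r2 <- shoot_once(p2, 0)
  expect_true(r2$stable)
  expect_gt(abs(r2$delta), 1e-6 * 150 * p2$Cb_in)
})

test_that("residual is non-decreasing in the guess across stable shots", {
  p <- single_pass_problem(fixture_setup("f3_qd150"))
  guesses <- seq(-150 * p$Cb_in, 0, length.out = 25)
  res <- vapply(guesses, function(g) shoot_once(p, g)$delta, numeric(1))
  stable <- vapply(guesses, function(g) shoot_once(p, g)$stable, logical(1))
  expect_true(all(diff(res[stable]) > -1e-12 * max(abs(res))))
})

test_that("interval classification follows the priority taxonomy", {
  cls <- function(d, s) classify_interval(d, s)
  # clean sign changes and the positive-to-smaller-positive signature
  expect_equal(cls(c(-3, 2), c(TRUE, TRUE))[c("type", "priority")],
               list(type = "1", priority = "high"))
  expect_equal(cls(c(3, -2), c(TRUE, TRUE))$type, "2")
  expect_equal(cls(c(5, 2), c(TRUE, TRUE))[c("type", "priority")],
               list(type = "7", priority = "high"))
  # monotone increase is the expected stable pattern: not an interval
  expect_true(is.na(cls(c(5, 8), c(TRUE, TRUE))$type))
  expect_true(is.na(cls(c(-5, -2), c(TRUE, TRUE))$type))
  # instability bridging
  expect_equal(cls(c(-3, NA, 2), c(TRUE, FALSE, TRUE))[c("type", "priority")],
               list(type = "3", priority = "low"))
  expect_equal(cls(c(3, NA, -2), c(TRUE, FALSE, TRUE))$type, "4")
  expect_equal(cls(c(-3, NA), c(TRUE, FALSE))[c("type", "priority")],
               list(type = "5", priority = "low"))
  expect_equal(cls(c(NA, 2), c(FALSE, TRUE))$type, "6")
  # positive to smaller positive across instability: partial vs total
  expect_equal(cls(c(5, NA, 3, NA, 2), c(TRUE, FALSE, TRUE, FALSE, TRUE))$type,
               "8a")
  expect_equal(cls(c(5, NA, NA, 2), c(TRUE, FALSE, FALSE, TRUE))[
    c("type", "priority")], list(type = "8b", priority = "low"))
})

test_that("full sweeps are partitioned into classified intervals", {
  xy0 <- seq(-8, 0, 1)
  delta <- c(-6, -4, NA, NA, 1, 3, 2.5, NA, 2)
  stable <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  spans <- albudial:::find_intervals(xy0, delta, stable)
  types <- vapply(spans, function(s) s$type, character(1))
  # bridge with sign change (3), clean 7, and an 8b bridge
  expect_setequal(types, c("3", "7", "8b"))
  ordered <- albudial:::order_intervals(spans)
  pri <- vapply(ordered, function(s) s$priority, character(1))
  # all high-priority intervals queue ahead of all low-priority ones
  expect_equal(pri, pri[order(match(pri, c("high", "low")))])
  expect_equal(pri[1], "high")
})

test_that("solve_single_pass matches the independent dense BVP oracle", {
  # the central correctness property, at bench scale on two fixtures here
  # (all five are exercised by the acceptance suite)
  for (name in c("f3_qd150", "f3_qd20")) {
    p <- single_pass_problem(fixture_setup(name))
    sp <- solve_single_pass(p)
    ref <- oracle_pass_xy0(p)
    expect_lt(abs(sp$xy0 - ref) / abs(ref), 1e-3)
    expect_lte(sp$xy0, 0)
    expect_lt(sp$residual, 1e-8 * 150 * p$Cb_in * 1.01)
  }
})

test_that("no transport means no removal; removal is bounded by supply and equilibrium", {
  s <- no_transport_setup()
  p0 <- single_pass_problem(s, KfreeA_eff = 0)
  sp0 <- solve_single_pass(p0)
  expect_equal(sp0$xy0, 0, tolerance = 1e-12)
  expect_equal(sp0$Cb_out, p0$Cb_in, tolerance = 1e-12)
  expect_equal(sp0$Cd_out, p0$Cd_in, tolerance = 1e-12)

  p <- single_pass_problem(fixture_setup("f3_qd150"))
  sp <- solve_single_pass(p)
  expect_lte(abs(sp$xy0), 150 * p$Cb_in)
  # free concentrations must not cross: blood outlet free still above
  # dialysate outlet free
  KB <- p$setup$solute$KB
  free_b_out <- free_toxin(sp$Cb_out, p$Catlb_in, KB)
  free_d_out <- free_toxin(sp$Cd_out, p$Catld_in, KB)
  expect_gt(free_b_out, 0)
  expect_lt(sp$Cb_out, p$Cb_in)
})

test_that("chi reconstruction conserves mass between the two sides", {
  p <- single_pass_problem(fixture_setup("f3_qd20"))
  sp <- solve_single_pass(p)
  prof <- sp$profile
  arr <- albudial:::pass_arrays(p)
  # blood-side loss and dialysate-side gain reconstruct the same chi
  chi_blood <- prof$Cstlb * arr$Qb - arr$Qb_in * arr$Cb_in
  Cd_out <- arr$Cd_in - sp$xy0 / arr$Qd_in
  chi_dial <- prof$Cstld * arr$Qd - Cd_out * arr$Qd_in
  expect_equal(chi_blood, chi_dial, tolerance = 1e-10)
  expect_equal(chi_blood, prof$chi, tolerance = 1e-10)
})

test_that("halving the spatial step moves xy0 by far less than 0.05%", {
  s <- fixture_setup("f3_qd150")
  p1 <- single_pass_problem(s, max_step_mm = 1)
  p2 <- single_pass_problem(s, max_step_mm = 0.5)
  x1 <- solve_single_pass(p1)$xy0
  x2 <- solve_single_pass(p2)$xy0
  expect_lt(abs(x1 - x2) / abs(x1), 5e-4)
})

test_that("debug traces can be dumped for shooting diagnostics", {
  p <- single_pass_problem(fixture_setup("f3_qd150"))
  sp <- solve_single_pass(p, debug = TRUE)
  path <- tempfile(fileext = ".csv")
  write_shooting_trace(sp, path)
  dumped <- utils::read.csv(path)
  expect_true(all(c("sweep", "xy0", "delta", "stable") %in% names(dumped)))
  expect_gt(nrow(dumped), 10)
  sp2 <- solve_single_pass(p)
  expect_error(write_shooting_trace(sp2, path), "debug")
})
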