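series <- function(t, v) data.frame(time_min = t, concentration_mg_dl = v)

test_that("goodness-of-fit criteria match their closed forms", {
  t <- seq(0, 180, 30)
  a <- series(t, seq(15, 9, length.out = 7))
  expect_identical(sum_of_squares_error(a, a), 0)
  expect_identical(final_percent_error(a, a), 0)
  # constant offset d over n points gives n d^2
  b <- a; b$concentration_mg_dl <- a$concentration_mg_dl + 0.5
  expect_equal(sum_of_squares_error(b, a), 7 * 0.25, tolerance = 1e-12)
  # permuting the point order leaves the sum unchanged
  p <- sample(7)
  expect_equal(sum_of_squares_error(b[p, ], a[p, ]),
               sum_of_squares_error(b, a), tolerance = 1e-12)
  # signed percent error: +10% when the model over-predicts by 10%
  c10 <- a; c10$concentration_mg_dl[7] <- a$concentration_mg_dl[7] * 1.1
  expect_equal(final_percent_error(c10, a), 10, tolerance = 1e-10)
  # and negative when the model under-predicts the final value
  c90 <- a; c90$concentration_mg_dl[7] <- a$concentration_mg_dl[7] * 0.9
  expect_lt(final_percent_error(c90, a), 0)
  # mismatched grids are an alignment error, not an interpolation
  bad <- series(t + 1, a$concentration_mg_dl)
  expect_error(sum_of_squares_error(bad, a), "alignment")
  expect_error(final_percent_error(series(0, 0), series(0, 0)), "zero")
})

test_that("grid constructor validates and warns on out-of-bound values", {
  g <- fit_grid(c(0.5e7, 1.5e7), c(500, 1000), 0.45)
  expect_s3_class(g, "fit_grid")
  expect_error(fit_grid(c(2e7, 1e7), c(500)), "increasing")
  expect_warning(fit_grid(c(0.5e7, 8e7), c(500, 1000)), "bounds")
})

test_that("noiseless self-consistency: the sweep recovers the generating point", {
  s <- quick_setup(duration_h = 1)
  truth <- list(KB = 1.5e7, KfreeA_at_500 = 1000)
  t_samp <- seq(0, 60, 15)
  clean <- simulate_session(update_setup(s, KB = truth$KB,
                                         KfreeA_at_500 = truth$KfreeA_at_500),
                            t_end_min = 60, out_times_min = t_samp)
  grid <- fit_grid(c(0.5e7, 1.5e7, 2.5e7), c(500, 1000, 1500), 0.45)
  for (crit in c("sum_of_squares", "final_percent_error")) {
    fit <- sweep_fit(s, clean, grid, criterion = crit)
    expect_equal(fit$best_params$KB, truth$KB)
    expect_equal(fit$best_params$KfreeA_at_500, truth$KfreeA_at_500)
    # the error surface is exactly zero at the generating grid point
    expect_lt(fit$best_params$error, 1e-8)
    # and the reported minimum matches its own surface
    expect_equal(min(fit$surface$error), fit$best_params$error)
  }
})

test_that("sweep bookkeeping: determinism, tie-breaking, failure records", {
  s <- quick_setup(duration_h = 0.5)
  t_samp <- c(0, 15, 30)
  clean <- simulate_session(s, t_end_min = 30, out_times_min = t_samp)
  # identical model at two beta values when Qd = 500-equivalent degeneracy is
  # not available here, so force a tie with a flat criterion: measured equal
  # to model at both grid betas is impossible; instead check determinism
  grid <- fit_grid(c(0.5e7, 1.5e7), c(500, 1000))
  f1 <- sweep_fit(s, clean, grid)
  f2 <- sweep_fit(s, clean, grid)
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$surface$error, f2$surface$error)

  # surfaces carry every grid point in a stable order
  expect_equal(nrow(f1$surface), 4)
  expect_identical(f1$surface[c("KB", "KfreeA_at_500", "beta_Qd")],
                   tidyr::expand_grid(KB = c(0.5e7, 1.5e7),
                                      KfreeA_at_500 = c(500, 1000),
                                      beta_Qd = 0.05544))

  # glance/tidy accessors
  expect_equal(nrow(glance(f1)), 1)
  expect_equal(nrow(tidy(f1)), 4)
})

test_that("exact error ties break toward the smallest parameters", {
  # construct a degenerate two-point tie by scoring against a measured
  # series the model cannot distinguish: beta has no effect when the
  # session's dialysate flow equals the 500 mL/min reference
  s <- quick_setup(Qd = 500, duration_h = 0.5, Vd = 500)
  t_samp <- c(0, 15, 30)
  clean <- simulate_session(s, t_end_min = 30, out_times_min = t_samp)
  grid <- fit_grid(5e6, 769.23, c(0, 0.3, 0.6))
  fit <- sweep_fit(s, clean, grid)
  # all beta values give identical sessions at Qd = 500: smallest beta wins
  expect_equal(fit$best_params$beta_Qd, 0)
  expect_lt(max(fit$surface$error) - min(fit$surface$error), 1e-12)
})
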