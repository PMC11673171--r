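# Grid-sweep estimation of the binding constant KB, the reference
# conductance KfreeA at 500 mL/min, and its flow-dependence beta_Qd, scored
# by either of two goodness-of-fit criteria: the sum of squared residuals
# over the whole trace, or the percent error of the final concentration.

# coerce a time series to a two-column tibble (time_min, conc)
as_series <- function(x) {
  if (inherits(x, "session_trace")) {
    return(tibble::tibble(time_min = x$t, conc = x$Cb))
  }
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("a time series needs a time and a concentration column",
                        call. = FALSE)
  tibble::tibble(time_min = x[[1]], conc = x[[2]])
}

check_aligned <- function(model, measured) {
  if (nrow(model) != nrow(measured) ||
      !isTRUE(all.equal(model$time_min, measured$time_min))) {
    stop("alignment error: model and measured series must share the same time grid ",
         "(no implicit interpolation)", call. = FALSE)
  }
}

#' Sum-of-squares goodness of fit
#'
#' `sum_i (Cmodel(t_i) - Ctrue(t_i))^2` over a shared time grid. The two
#' series must be sampled at identical times; no interpolation is performed.
#'
#' @param model,measured Time series: a `session_trace` or a data frame whose
#'   first two columns are time (min) and concentration (mg/dL).
#' @return Scalar error, (mg/dL)^2.
#' @export
sum_of_squares_error <- function(model, measured) {
  model <- as_series(model); measured <- as_series(measured)
  check_aligned(model, measured)
  sum((model$conc - measured$conc)^2)
}

#' Percent error of the final concentration
#'
#' `100 * (Cmodel(t_end) - Ctrue(t_end)) / Ctrue(t_end)`. Signed: negative
#' when the model under-predicts the measured final concentration.
#'
#' @inheritParams sum_of_squares_error
#' @return Signed percent error.
#' @export
final_percent_error <- function(model, measured) {
  model <- as_series(model); measured <- as_series(measured)
  check_aligned(model, measured)
  m_end <- model$conc[nrow(model)]
  t_end <- measured$conc[nrow(measured)]
  if (t_end == 0) {
    stop("division error: measured final concentration is zero", call. = FALSE)
  }
  100 * (m_end - t_end) / t_end
}

#' Parameter grid for sweep fitting
#'
#' The search space the sweep enumerates. The physically sensible bounds are
#' KB in [0.5e7, 7.5e7] 1/M, conductance in [100, 2500] mL/min, and beta_Qd
#' in [0, 0.6]; values outside them trigger a warning but the sweep proceeds
#' (soft bound).
#'
#' @param kb_values Strictly increasing KB candidates, 1/M.
#' @param kfreeA_values Strictly increasing conductance candidates, mL/min.
#' @param beta_values Strictly increasing beta_Qd candidates (default: the
#'   single literature value 0.05544).
#' @return An object of class `fit_grid`.
#' @export
fit_grid <- function(kb_values, kfreeA_values, beta_values = 0.05544) {
  chk <- function(x, name) {
    if (!length(x) || is.unsorted(x, strictly = TRUE)) {
      stop("invalid grid: ", name, " must be non-empty and strictly increasing",
           call. = FALSE)
    }
  }
  chk(kb_values, "kb_values"); chk(kfreeA_values, "kfreeA_values")
  chk(beta_values, "beta_values")
  if (min(kb_values) < 0.5e7 || max(kb_values) > 7.5e7 ||
      min(kfreeA_values) < 100 || max(kfreeA_values) > 2500 ||
      min(beta_values) < 0 || max(beta_values) > 0.6) {
    warning("fit grid extends outside the standard search bounds; proceeding")
  }
  structure(list(kb_values = kb_values, kfreeA_values = kfreeA_values,
                 beta_values = beta_values), class = "fit_grid")
}

#' Replace fitted parameters in a setup
#'
#' @param setup A [dialysis_setup()].
#' @param KB,KfreeA_at_500,beta_Qd New values (NULL keeps the current one).
#' @return The modified setup.
#' @export
update_setup <- function(setup, KB = NULL, KfreeA_at_500 = NULL,
                         beta_Qd = NULL) {
  stopifnot(inherits(setup, "dialysis_setup"))
  if (!is.null(KB)) {
    setup$solute <- solute_system(KB, setup$solute$mw_toxin,
                                  setup$solute$mw_binder)
  }
  tr <- setup$transport
  if (!is.null(KfreeA_at_500) || !is.null(beta_Qd)) {
    setup$transport <- transport_coefficients(
      KfreeA_at_500 %||% tr$KfreeA_at_500,
      beta_Qd %||% tr$beta_Qd
    )
  }
  setup
}

#' Grid-sweep parameter fit
#'
#' Simulates every grid point and returns the one minimising the chosen
#' goodness-of-fit criterion, together with the full error surface. With
#' several conditions (e.g. the same dialyzer at several dialysate flow
#' rates, for fitting `beta_Qd`) the per-condition errors are summed;
#' for the final-percent-error criterion the summed quantity is the absolute
#' percent error, so the single-condition surface is `|percent error|`.
#' A grid point whose simulation fails records an infinite error with a
#' message rather than aborting the sweep. The result is deterministic and
#' independent of grid evaluation order; exact ties are broken toward the
#' smallest KB, then conductance, then beta.
#'
#' @param setup A [dialysis_setup()], or a list of setups (one per measured
#'   condition).
#' @param measured A time series as in [sum_of_squares_error()] (replicate
#'   measurements must be averaged or fit separately by the caller), or a
#'   list of series matching `setup`.
#' @param grid A [fit_grid()].
#' @param criterion `"sum_of_squares"` or `"final_percent_error"`.
#' @param max_step_mm,max_dt_s Discretisation controls forwarded to
#'   [simulate_session()].
#' @return An object of class `dialysis_fit`: `best_params` (one-row tibble),
#'   `surface` (tibble `KB`, `KfreeA_at_500`, `beta_Qd`, `error`),
#'   `criterion`.
#' @export
sweep_fit <- function(setup, measured, grid,
                      criterion = c("sum_of_squares", "final_percent_error"),
                      max_step_mm = 1, max_dt_s = 100) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(grid, "fit_grid"))
  setups <- if (inherits(setup, "dialysis_setup")) list(setup) else setup
  stopifnot(all(vapply(setups, inherits, logical(1), "dialysis_setup")))
  series <- if (is.data.frame(measured) || inherits(measured, "session_trace")) {
    list(as_series(measured))
  } else {
    lapply(measured, as_series)
  }
  if (length(series) != length(setups)) {
    stop("alignment error: need one measured series per setup", call. = FALSE)
  }

  points <- tidyr::expand_grid(
    KB = grid$kb_values,
    KfreeA_at_500 = grid$kfreeA_values,
    beta_Qd = grid$beta_values
  )
  score_point <- function(KB, KfreeA_at_500, beta_Qd) {
    total <- 0
    for (k in seq_along(setups)) {
      s <- update_setup(setups[[k]], KB = KB, KfreeA_at_500 = KfreeA_at_500,
                        beta_Qd = beta_Qd)
      tr <- tryCatch(
        simulate_session(s, t_end_min = max(series[[k]]$time_min),
                         out_times_min = series[[k]]$time_min,
                         max_step_mm = max_step_mm, max_dt_s = max_dt_s),
        error = function(e) {
          message("grid point (KB=", KB, ", kA=", KfreeA_at_500, ", beta=",
                  beta_Qd, ") failed: ", conditionMessage(e))
          NULL
        }
      )
      if (is.null(tr)) return(Inf)
      total <- total + switch(
        criterion,
        sum_of_squares = sum_of_squares_error(tr, series[[k]]),
        final_percent_error = abs(final_percent_error(tr, series[[k]]))
      )
    }
    total
  }
  points$error <- purrr::pmap_dbl(points, score_point)

  best <- dplyr::arrange(points, .data$error, .data$KB, .data$KfreeA_at_500,
                         .data$beta_Qd)[1, ]
  if (!is.finite(best$error)) {
    stop("sweep failed: no grid point produced a finite error", call. = FALSE)
  }
  structure(list(best_params = best, surface = points, criterion = criterion),
            class = "dialysis_fit")
}

#' @export
print.dialysis_fit <- function(x, ...) {
  b <- x$best_params
  cat("<dialysis_fit> criterion:", x$criterion, "\n")
  cat(sprintf("  best: KB = %.3g 1/M, KfreeA(500) = %g mL/min, beta_Qd = %g\n",
              b$KB, b$KfreeA_at_500, b$beta_Qd))
  cat(sprintf("  error at minimum: %.6g over %d grid points\n",
              b$error, nrow(x$surface)))
  invisible(x)
}

#' @export
tidy.dialysis_fit <- function(x, ...) x$surface

#' @export
glance.dialysis_fit <- function(x, ...) {
  dplyr::mutate(x$best_params, criterion = x$criterion,
                n_grid = nrow(x$surface))
}

#' Plot a fit error surface
#'
#' Heat map of the error over KB and conductance, faceted by beta when the
#' beta grid has more than one value.
#'
#' @param object A `dialysis_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dialysis_fit <- function(object, ...) {
  s <- object$surface
  if (length(unique(s$KB)) > 1 && length(unique(s$KfreeA_at_500)) > 1) {
    p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$KfreeA_at_500, y = .data$KB,
                                         fill = log10(.data$error))) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "KfreeA at 500 mL/min (mL/min)", y = "KB (1/M)",
                    fill = paste0("log10 ", object$criterion))
    if (length(unique(s$beta_Qd)) > 1) {
      p <- p + ggplot2::facet_wrap(~beta_Qd)
    }
    p
  } else {
    xvar <- if (length(unique(s$beta_Qd)) > 1) "beta_Qd" else "KfreeA_at_500"
    ggplot2::ggplot(s, ggplot2::aes(x = .data[[xvar]], y = .data$error)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = xvar, y = object$criterion)
  }
}

#' Read a measured concentration series from CSV
#'
#' Expected schema: columns `time_min` and `concentration_mg_dl` (an optional
#' `replicate` column is allowed and preserved).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_measured_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_min", "concentration_mg_dl")
  if (!all(need %in% names(df))) {
    stop("schema mismatch: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}
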