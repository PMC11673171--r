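# Counter-current single-pass boundary-value problem in the amount-removed
# (chi) formulation, solved by the modified shooting method: equally spaced
# guesses of the removed amount xy0 at the dialysate inlet, interval
# classification of the residual pattern, and a breadth-first priority search
# that refines high-priority intervals with a coarse subdivision and
# low-priority (instability-bridging) intervals with a fine one.

#' Set up a single-pass problem
#'
#' Assembles everything one quasi-steady pass needs: the analytic hydraulic
#' field, inlet compositions in molar units, binder profiles (albumin
#' concentration scales inversely with local flow, since each side's albumin
#' is conserved), and the flow-adjusted conductance. Inlet concentrations
#' default to the operating point's starting values; during a session the
#' reservoir concentrations are passed instead.
#'
#' @param setup A [dialysis_setup()].
#' @param Cb_total Total toxin at the blood inlet, mol/L (default: operating
#'   point start value).
#' @param Cd_total Total toxin at the dialysate inlet, mol/L (default:
#'   operating point start value).
#' @param max_step_mm Maximum spatial step for the integrator, mm (default 1).
#' @param KfreeA_eff Effective conductance, mL/min; by default the
#'   flow-adjusted value [kfreeA_at_flow()] at the session's dialysate inlet
#'   flow.
#' @return An object of class `single_pass_problem`.
#' @export
single_pass_problem <- function(setup, Cb_total = NULL, Cd_total = NULL,
                                max_step_mm = 1, KfreeA_eff = NULL) {
  stopifnot(inherits(setup, "dialysis_setup"))
  op <- setup$operating; sol <- setup$solute
  if (is.null(Cb_total)) {
    Cb_total <- clinical_to_molar(op$Cb_toxin0, sol$mw_toxin, "mg/dL")
  }
  if (is.null(Cd_total)) {
    Cd_total <- clinical_to_molar(op$Cd_toxin0, sol$mw_toxin, "mg/dL")
  }
  if (Cb_total < 0 || Cd_total < 0) {
    stop("invalid parameter: inlet concentrations must be >= 0", call. = FALSE)
  }
  if (is.null(KfreeA_eff)) {
    KfreeA_eff <- kfreeA_at_flow(setup$transport, op$Qd_in)
  }
  field <- axial_hydraulics_field(setup$geometry, setup$fluids,
                                  op$Qb_in, op$Qd_in)
  structure(list(
    setup = setup,
    field = field,
    Cb_in = Cb_total,
    Cd_in = Cd_total,
    Catlb_in = clinical_to_molar(op$Cb_albumin, sol$mw_binder, "g/dL"),
    Catld_in = clinical_to_molar(op$Cd_albumin, sol$mw_binder, "g/dL"),
    KfreeA_eff = KfreeA_eff,
    sigma = setup$geometry$sigma,
    max_step_mm = max_step_mm
  ), class = "single_pass_problem")
}

# node arrays handed to the compiled integrator; h_factor < 1 refines the grid
pass_arrays <- function(p, h_factor = 1) {
  L <- p$setup$geometry$fiber_length
  h_req <- p$max_step_mm * 1e-3 * h_factor
  n_seg <- max(2L, as.integer(ceiling(L / h_req)))
  z <- seq(0, L, length.out = n_seg + 1L)
  Qb <- p$field$Qb(z) * .ML_MIN_PER_M3_S
  Qd <- p$field$Qd(z) * .ML_MIN_PER_M3_S
  if (any(Qd <= 0) || any(Qb <= 0)) {
    stop("invalid operating point: local flow becomes non-positive along the fiber",
         call. = FALSE)
  }
  op <- p$setup$operating
  list(
    Qb = Qb, Qd = Qd,
    Jv_m = p$field$kJ * p$field$u(z) * .ML_MIN_PER_M3_S,
    Catlb = p$Catlb_in * op$Qb_in / Qb,
    Catld = p$Catld_in * op$Qd_in / Qd,
    h = z[2] - z[1], L = L, sigma = p$sigma, kA = p$KfreeA_eff,
    KB = p$setup$solute$KB,
    Qb_in = op$Qb_in, Cb_in = p$Cb_in,
    Qd_in = op$Qd_in, Cd_in = p$Cd_in
  )
}

#' Integrate one shooting guess
#'
#' Integrates the amount-removed variable chi from the dialysate inlet
#' (z = L, where chi equals the guessed removal `xy0_guess`) down to the
#' blood inlet (z = 0, where chi is known to vanish) and returns the signed
#' residual `Delta = chi(0)`. Integration blow-up, non-finite state or
#' physically impossible reconstructed concentrations are not errors: the
#' guess is reported as unstable, which is data for the interval classifier.
#'
#' @param p A [single_pass_problem()].
#' @param xy0_guess Guessed amount removed over the pass (M mL/min,
#'   non-positive by convention).
#' @param h_factor Spatial-step multiplier (0.5 integrates at half the step
#'   for spurious-root checks).
#' @return A list with `delta` (signed residual, M mL/min) and `stable`
#'   (logical).
#' @export
shoot_once <- function(p, xy0_guess, h_factor = 1) {
  stopifnot(inherits(p, "single_pass_problem"))
  res <- .shoot_batch_cpp(pass_arrays(p, h_factor), as.numeric(xy0_guess))
  list(delta = res$delta[1], stable = res$stable[1])
}

.INTERVAL_PRIORITY <- c("1" = "high", "2" = "high", "7" = "high", "8a" = "high",
                        "3" = "low", "4" = "low", "5" = "low", "6" = "low",
                        "8b" = "low")

#' Classify a shooting-guess interval
#'
#' Classifies an ordered run of shooting guesses (by increasing `xy0`) into
#' the interval taxonomy that drives the priority search. For a stable
#' system the residual increases with the guess, so a sign change (types 1
#' and 2) or a positive-to-smaller-positive pattern (type 7 — impossible
#' without instability, hence a hidden zero crossing) is worth refining at
#' high priority. Runs bridging unstable guesses (types 3-6, 8b) are searched
#' later with a finer step so small islands of stability near the true zero
#' are not missed; a positive-to-smaller-positive run whose interior is only
#' partially unstable (8a) keeps high priority. Runs showing the expected
#' stable monotone pattern are not intervals and return type `NA`.
#'
#' @param delta Residuals of the guesses in the run (ordered by `xy0`).
#' @param stable Logical stability flags, same length.
#' @return A list with `type` (character: `"1"`, `"2"`, `"3"`, `"4"`, `"5"`,
#'   `"6"`, `"7"`, `"8a"`, `"8b"`, or `NA` for a non-interval) and `priority`
#'   (`"high"`, `"low"`, or `NA`).
#' @examples
#' classify_interval(c(-3, 2), c(TRUE, TRUE))   # type 1, high priority
#' classify_interval(c(5, 2), c(TRUE, TRUE))    # type 7, high priority
#' classify_interval(c(5, 8), c(TRUE, TRUE))    # not an interval
#' @export
classify_interval <- function(delta, stable) {
  n <- length(delta)
  stopifnot(n >= 2, length(stable) == n)
  out <- function(type) {
    list(type = type,
         priority = if (is.na(type)) NA_character_ else unname(.INTERVAL_PRIORITY[type]))
  }
  d1 <- delta[1]; dn <- delta[n]
  s1 <- stable[1]; sn <- stable[n]
  interior <- if (n > 2) stable[2:(n - 1)] else logical(0)

  if (s1 && sn) {
    clean <- !length(interior) || all(interior)
    if (clean) {
      if (d1 < 0 && dn >= 0) return(out("1"))
      if (d1 >= 0 && dn < 0) return(out("2"))
      if (d1 > 0 && dn > 0 && dn < d1) return(out("7"))
      return(out(NA_character_))
    }
    if (d1 < 0 && dn >= 0) return(out("3"))
    if (d1 >= 0 && dn < 0) return(out("4"))
    if (d1 > 0 && dn > 0 && dn < d1) {
      return(out(if (any(interior)) "8a" else "8b"))
    }
    return(out(NA_character_))
  }
  if (s1 && !sn && d1 < 0 && !any(c(interior, sn))) return(out("5"))
  if (!s1 && sn && dn > 0 && !any(c(s1, interior))) return(out("6"))
  out(NA_character_)
}

# Scan a full sweep for candidate intervals. Returns a list of spans, each
# with bound indices, type, priority, and the distance of its (stable)
# bounds' residuals from the target Delta = 0.
find_intervals <- function(xy0, delta, stable) {
  n <- length(xy0)
  idx_stable <- which(stable)
  spans <- list()
  add <- function(i, j) {
    cls <- classify_interval(delta[i:j], stable[i:j])
    if (!is.na(cls$type)) {
      dist <- suppressWarnings(
        min(abs(delta[c(i, j)][stable[c(i, j)]]), na.rm = TRUE)
      )
      spans[[length(spans) + 1L]] <<- list(
        lower = xy0[i], upper = xy0[j], i = i, j = j,
        type = cls$type, priority = cls$priority,
        dist = if (is.finite(dist)) dist else Inf
      )
    }
  }
  if (length(idx_stable) >= 2) {
    for (k in seq_len(length(idx_stable) - 1L)) {
      add(idx_stable[k], idx_stable[k + 1L])
    }
  }
  if (length(idx_stable)) {
    first <- idx_stable[1]; last <- idx_stable[length(idx_stable)]
    if (first > 1) add(1L, first)         # leading unstable run (type 6)
    if (last < n) add(last, n)            # trailing unstable run (type 5)
  }
  spans
}

# order: high priority first; within class by residual distance to target;
# ties broken toward the bound of smaller |xy0| (less removal is conservative)
order_intervals <- function(spans) {
  if (!length(spans)) return(spans)
  pri <- vapply(spans, function(s) s$priority, character(1))
  dist <- vapply(spans, function(s) s$dist, numeric(1))
  mag <- vapply(spans, function(s) abs(s$upper), numeric(1))
  spans[order(match(pri, c("high", "low")), dist, mag)]
}

#' Solve the counter-current single pass
#'
#' Finds the amount of toxin removed over one quasi-steady pass through the
#' dialyzer by the modified shooting method. Equally spaced guesses of `xy0`
#' over `[-Qb_in * Cb_in, 0]` (no more toxin can be removed than the blood
#' stream carries) are integrated and their residuals classified into
#' intervals ([classify_interval()]); up to 13 intervals per generation are
#' refined breadth-first, high-priority intervals with a coarse (10-fold)
#' subdivision and low-priority ones with a fine (100-fold) subdivision.
#' A candidate root must reproduce when re-integrated at half the spatial
#' step, which rejects spurious zero crossings caused by numerical
#' instability.
#'
#' @param p A [single_pass_problem()].
#' @param n_guesses Number of first-generation guesses (>= 3, default 25).
#' @param tol Residual tolerance on `|Delta|` (M mL/min); default
#'   `1e-8 * Qb_in * max(Cb_in, Cd_in)`.
#' @param max_generations Cap on refinement generations (default 60).
#' @param max_intervals Intervals searched per generation (default 13).
#' @param hint Optional previous-root warm start: the first sweep is narrowed
#'   around it and widened automatically if the root escapes.
#' @param debug If `TRUE`, attach the full guess/residual/classification
#'   trace for diagnostics.
#' @return An object of class `single_pass_solution`: list with `xy0` (amount
#'   removed, M mL/min, non-positive), `residual`, `Cb_out`, `Cd_out` (outlet
#'   totals, M), `profile` (tibble of `z`, `chi`, `Cstlb`, `Cstld`), and
#'   `n_shoots`.
#' @export
solve_single_pass <- function(p, n_guesses = 25, tol = NULL,
                              max_generations = 60, max_intervals = 13,
                              hint = NULL, debug = FALSE) {
  stopifnot(inherits(p, "single_pass_problem"), n_guesses >= 3)
  arrays <- pass_arrays(p)
  arrays_half <- pass_arrays(p, 0.5)
  core <- solve_pass_core(arrays, arrays_half, tol = tol,
                          n_guesses = n_guesses,
                          max_generations = max_generations,
                          max_intervals = max_intervals,
                          hint = hint, debug = debug)
  pass_solution(arrays, core)
}

# assemble the user-facing solution object from a converged core result
pass_solution <- function(arrays, core) {
  prof <- .shoot_profile_cpp(arrays, core$xy0)
  z <- seq(0, arrays$L, length.out = length(prof$chi))
  Cd_out <- arrays$Cd_in - core$xy0 / arrays$Qd_in
  profile <- tibble::tibble(
    z = z,
    chi = prof$chi,
    Cstlb = (arrays$Qb_in * arrays$Cb_in + prof$chi) / arrays$Qb,
    Cstld = (prof$chi + Cd_out * arrays$Qd_in) / arrays$Qd
  )
  structure(list(
    xy0 = core$xy0,
    residual = abs(core$delta),
    Cb_out = profile$Cstlb[nrow(profile)],
    Cd_out = profile$Cstld[1],
    profile = profile,
    n_shoots = core$n_shoots,
    trace = core$trace
  ), class = "single_pass_solution")
}

# Modified-shooting search over precomputed node arrays. Kept separate from
# the problem object so a session can update the two inlet scalars and reuse
# the (composition-independent) hydraulic arrays across time steps.
solve_pass_core <- function(arrays, arrays_half, tol = NULL, n_guesses = 25,
                            max_generations = 60, max_intervals = 13,
                            hint = NULL, debug = FALSE) {
  amount_in <- arrays$Qb_in * arrays$Cb_in
  scale <- max(amount_in, arrays$Qd_in * arrays$Cd_in, .Machine$double.xmin)
  if (is.null(tol)) tol <- 1e-8 * scale
  stopifnot(tol > 0, n_guesses >= 3)
  n_shoots <- 0L
  trace <- if (debug) list() else NULL

  sweep <- function(lo, hi, n) {
    g <- seq(lo, hi, length.out = n)
    res <- .shoot_batch_cpp(arrays, g)
    n_shoots <<- n_shoots + n
    if (debug) trace[[length(trace) + 1L]] <<- tibble::tibble(
      xy0 = g, delta = res$delta, stable = res$stable
    )
    list(xy0 = g, delta = res$delta, stable = res$stable)
  }

  verify_root <- function(xy0) {
    res <- .shoot_batch_cpp(arrays_half, xy0)
    n_shoots <<- n_shoots + 1L
    isTRUE(res$stable[1]) &&
      abs(res$delta[1]) < max(100 * tol, 1e-3 * scale)
  }

  best_of <- function(sw) {
    ok <- sw$stable & is.finite(sw$delta)
    if (!any(ok)) return(NULL)
    k <- which(ok)[which.min(abs(sw$delta[ok]))]
    list(xy0 = sw$xy0[k], delta = sw$delta[k])
  }

  lo_full <- -amount_in
  hi_full <- 0
  # warm start: narrow band around the previous root, widened on failure
  ranges <- list(c(lo_full, hi_full))
  n_first <- n_guesses
  if (!is.null(hint) && is.finite(hint)) {
    w <- max(0.005 * abs(hint), 1e-5 * scale)
    ranges <- list(c(max(hint - w, lo_full), min(hint + w, hi_full)),
                   c(lo_full, hi_full))
    n_first <- min(n_guesses, 7L)
  }

  solution <- NULL
  best_seen <- NULL
  for (range in ranges) {
    if (range[1] >= range[2]) next
    sw <- sweep(range[1], range[2], n_first)
    n_first <- n_guesses
    spans <- order_intervals(find_intervals(sw$xy0, sw$delta, sw$stable))
    if (!length(spans) && range[1] == lo_full && range[2] == hi_full) {
      # full sweep at the fine step before giving up entirely
      sw <- sweep(range[1], range[2], n_guesses * 10)
      spans <- order_intervals(find_intervals(sw$xy0, sw$delta, sw$stable))
    }
    b <- best_of(sw)
    if (!is.null(b) && (is.null(best_seen) || abs(b$delta) < abs(best_seen$delta))) {
      best_seen <- b
    }
    if (!is.null(b) && abs(b$delta) < tol && verify_root(b$xy0)) {
      solution <- b
      break
    }
    gen <- 0L
    while (length(spans) && gen < max_generations && is.null(solution)) {
      gen <- gen + 1L
      take <- spans[seq_len(min(length(spans), max_intervals))]
      next_spans <- list()
      for (s in take) {
        n_sub <- if (s$priority == "high") 11L else 101L
        sub <- sweep(s$lower, s$upper, n_sub)
        b <- best_of(sub)
        if (!is.null(b) &&
            (is.null(best_seen) || abs(b$delta) < abs(best_seen$delta))) {
          best_seen <- b
        }
        if (!is.null(b) && abs(b$delta) < tol) {
          if (verify_root(b$xy0)) {
            solution <- b
            break
          }
        }
        next_spans <- c(next_spans,
                        find_intervals(sub$xy0, sub$delta, sub$stable))
      }
      spans <- order_intervals(next_spans)
    }
    if (!is.null(solution)) break
  }

  if (is.null(solution)) {
    # a residual already below tolerance without a bracketing interval is
    # accepted (e.g. the no-transport fixed point xy0 = 0)
    if (!is.null(best_seen) && abs(best_seen$delta) < tol &&
        verify_root(best_seen$xy0)) {
      solution <- best_seen
    } else {
      err <- structure(
        class = c("albudial_no_solution", "error", "condition"),
        list(message = paste0(
          "no single-pass solution found: best |Delta| = ",
          format(if (is.null(best_seen)) NA_real_ else abs(best_seen$delta)),
          " at tolerance ", format(tol)),
          call = sys.call(-1), best = best_seen, trace = trace)
      )
      stop(err)
    }
  }

  list(xy0 = solution$xy0, delta = solution$delta, n_shoots = n_shoots,
       trace = trace)
}

#' @export
print.single_pass_solution <- function(x, ...) {
  cat("<single_pass_solution>\n")
  cat(sprintf("  xy0 (amount removed): %.6g M mL/min\n", x$xy0))
  cat(sprintf("  residual |Delta|: %.3g; shots: %d\n", x$residual, x$n_shoots))
  cat(sprintf("  Cb_out: %.6g M, Cd_out: %.6g M\n", x$Cb_out, x$Cd_out))
  invisible(x)
}

#' @export
tidy.single_pass_solution <- function(x, ...) x$profile

#' Plot a single-pass solution
#'
#' Total toxin concentration profiles on both sides of the membrane and the
#' cumulative removed amount along the fiber.
#'
#' @param object A `single_pass_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.single_pass_solution <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profile, cols = c("Cstlb", "Cstld"),
                              names_to = "side", values_to = "conc")
  long$side <- ifelse(long$side == "Cstlb", "blood", "dialysate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$conc,
                                     colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (m)", y = "total toxin (M)", colour = NULL)
}

#' Export a shooting diagnostics dump
#'
#' Writes the guess grid, residuals and stability flags of a debug-enabled
#' solve to CSV (one row per shot, one block per sweep generation).
#'
#' @param sol A `single_pass_solution` obtained with `debug = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shooting_trace <- function(sol, path) {
  stopifnot(inherits(sol, "single_pass_solution"))
  if (is.null(sol$trace)) {
    stop("no trace recorded: call solve_single_pass(..., debug = TRUE)",
         call. = FALSE)
  }
  tr <- dplyr::bind_rows(sol$trace, .id = "sweep")
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
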