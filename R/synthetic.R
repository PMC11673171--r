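# Synthetic bench experiments: replicate reservoir time series with the
# statistical structure of the in vitro study (replicate-to-replicate
# variation of the starting composition, additive measurement noise), so
# fitting and validation are testable without external data.

#' Noise model for synthetic experiments
#'
#' Gaussian noise truncated at zero, the simplest model consistent with
#' reporting bench results as mean +/- SD: starting compositions vary
#' between replicates, and each sampled concentration carries i.i.d.
#' measurement error.
#'
#' @param measurement_sd Measurement noise SD, mg/dL (default 0.3).
#' @param initial_sd Named list of SDs for the starting composition draws:
#'   `Cb_toxin0` (mg/dL), `Cb_albumin`, `Cd_albumin` (g/dL). Missing entries
#'   default to 0 (that quantity is identical across replicates).
#' @param replicates Number of replicate runs (default 3, the bench study's
#'   n).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(0.3, list(Cb_toxin0 = 2.35), replicates = 3, seed = 1)
#' @export
noise_model <- function(measurement_sd = 0.3, initial_sd = list(),
                        replicates = 3, seed = 1) {
  sds <- list(Cb_toxin0 = 0, Cb_albumin = 0, Cd_albumin = 0)
  unknown <- setdiff(names(initial_sd), names(sds))
  if (length(unknown)) {
    stop("unknown initial_sd entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sds[names(initial_sd)] <- initial_sd
  if (measurement_sd < 0 || any(unlist(sds) < 0)) {
    stop("invalid noise model: SDs must be >= 0", call. = FALSE)
  }
  if (replicates < 1) stop("invalid noise model: replicates must be >= 1",
                           call. = FALSE)
  structure(list(measurement_sd = measurement_sd, initial_sd = sds,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate synthetic replicate time series for one condition
#'
#' For each replicate, draws the starting composition from the condition's
#' mean +/- SD (truncated at zero), simulates the session with the supplied
#' true parameters, and adds measurement noise at the sample times. With all
#' SDs zero and one replicate the output equals the deterministic simulation
#' exactly.
#'
#' @param setup A [dialysis_setup()] whose operating point carries the
#'   condition's mean starting composition.
#' @param true_params Optional named list overriding `KB`, `KfreeA_at_500`
#'   and/or `beta_Qd` (see [update_setup()]).
#' @param noise A [noise_model()].
#' @param sample_times_min Sampling schedule in minutes (default: every
#'   30 min from 0 to the session end).
#' @param ... Discretisation controls forwarded to [simulate_session()].
#' @return A tibble with columns `replicate`, `time_min`,
#'   `concentration_mg_dl` (noisy blood reservoir toxin). Attributes
#'   `noiseless` (list of clean `session_trace`s) and `initials` (tibble of
#'   drawn starting compositions).
#' @export
generate_condition <- function(setup, true_params = list(), noise,
                               sample_times_min = NULL, ...) {
  stopifnot(inherits(setup, "dialysis_setup"), inherits(noise, "noise_model"))
  setup <- update_setup(setup,
                        KB = true_params$KB,
                        KfreeA_at_500 = true_params$KfreeA_at_500,
                        beta_Qd = true_params$beta_Qd)
  op <- setup$operating
  if (is.null(sample_times_min)) {
    sample_times_min <- seq(0, op$duration_h * 60, by = 30)
  }
  set.seed(noise$seed)
  sds <- noise$initial_sd
  draws <- tibble::tibble(
    replicate = seq_len(noise$replicates),
    Cb_toxin0 = pmax(0, stats::rnorm(noise$replicates, op$Cb_toxin0,
                                     sds$Cb_toxin0)),
    Cb_albumin = pmax(0, stats::rnorm(noise$replicates, op$Cb_albumin,
                                      sds$Cb_albumin)),
    Cd_albumin = pmax(0, stats::rnorm(noise$replicates, op$Cd_albumin,
                                      sds$Cd_albumin))
  )
  clean <- vector("list", noise$replicates)
  rows <- vector("list", noise$replicates)
  for (r in seq_len(noise$replicates)) {
    s <- setup
    s$operating <- operating_point(
      Qb_in = op$Qb_in, Qd_in = op$Qd_in, Vb = op$Vb, Vd = op$Vd,
      Cb_toxin0 = draws$Cb_toxin0[r], Cb_albumin = draws$Cb_albumin[r],
      Cd_albumin = draws$Cd_albumin[r], Cd_toxin0 = op$Cd_toxin0,
      duration_h = op$duration_h
    )
    tr <- simulate_session(s, t_end_min = max(sample_times_min),
                           out_times_min = sample_times_min, ...)
    clean[[r]] <- tr
    noisy <- tr$Cb + stats::rnorm(length(tr$Cb), 0, noise$measurement_sd)
    rows[[r]] <- tibble::tibble(
      replicate = r, time_min = tr$t,
      concentration_mg_dl = pmax(0, noisy)
    )
  }
  structure(dplyr::bind_rows(rows),
            noiseless = clean, initials = draws,
            class = c("synthetic_condition", "tbl_df", "tbl", "data.frame"))
}

#' Write synthetic replicates in the measured-data CSV schema
#'
#' One CSV per replicate (`<stem>_rep<k>.csv`), matching the schema
#' [read_measured_csv()] expects.
#'
#' @param cond Output of [generate_condition()].
#' @param stem Output path stem.
#' @return The written paths, invisibly.
#' @export
write_condition_csv <- function(cond, stem) {
  paths <- character(0)
  for (r in unique(cond$replicate)) {
    sub <- cond[cond$replicate == r, c("time_min", "concentration_mg_dl")]
    path <- paste0(stem, "_rep", r, ".csv")
    utils::write.csv(sub, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
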