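# Seeded synthetic luminescence plates: ground-truth forward simulations
# plus additive Gaussian noise, for calibration and recovery experiments.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

.new_plate <- function(rows, params, noise_sd, noise_type, seed, mode,
                       kind) {
  rows$flagged_negative <- rows$reading < 0
  structure(rows,
            true_params = params, noise_sd = noise_sd,
            noise_type = noise_type, seed = seed, mode = mode,
            kind = kind, params_digest = params_digest(params),
            class = c("synthetic_plate", "data.frame"))
}

#' Generate synthetic endpoint dose-response luminescence data
#'
#' Simulates the biosensor's cumulative luminescence at `t_end` for each
#' initial ABA level (via [dose_response()]) and adds independent
#' additive Gaussian noise per replicate. The generating parameters,
#' noise level and seed are stored in the table's attributes, so recovery
#' experiments always know their ground truth. Negative noisy readings
#' are kept (clipping would bias estimators) and flagged.
#'
#' @param params A [biosensor_params()] object (`NULL` = reference set):
#'   the ground truth.
#' @param aba_levels Initial ABA concentrations, µM (default:
#'   [default_aba_levels()], 12 log-spaced levels over 1.5-50 µM).
#' @param replicates Replicates per level (>= 1).
#' @param noise_sd Noise standard deviation. With
#'   `noise_type = "absolute"` (default) in RLU; with
#'   `noise_type = "fraction"` as a fraction of each noiseless signal.
#' @param seed Integer seed; identical arguments and seed give an
#'   identical table.
#' @param settings [solver_settings()]; `t_end` is the endpoint readout
#'   time (default 3600 s).
#' @param mode Biosensor kinetics mode.
#' @param noise_type `"absolute"` or `"fraction"`.
#'
#' @return A `synthetic_plate`: data frame with columns `aba_initial`
#'   (µM), `replicate`, `time` (s), `reading` (RLU), `flagged_negative`;
#'   attributes `true_params`, `noise_sd`, `noise_type`, `seed`, `mode`,
#'   `params_digest`.
#'
#' @examples
#' plate <- generate_dose_response_data(replicates = 2, noise_sd = 0.5,
#'            seed = 7, settings = solver_settings(t_end = 600))
#' head(plate)
#' @export
generate_dose_response_data <- function(params = NULL,
                                        aba_levels = default_aba_levels(),
                                        replicates = 1, noise_sd = 0,
                                        seed = 1,
                                        settings = solver_settings(t_end = 3600),
                                        mode = "mass_action",
                                        noise_type = c("absolute",
                                                       "fraction")) {
  noise_type <- match.arg(noise_type)
  stopifnot(replicates >= 1, noise_sd >= 0)
  params <- .as_params(if (is.null(params)) biosensor_params() else params,
                       "biosensor_params", biosensor_params)
  dr <- dose_response(aba_levels, params, settings, mode)
  rows <- data.frame(
    aba_initial = rep(dr$aba_initial, each = replicates),
    replicate = rep(seq_len(replicates), times = nrow(dr)),
    time = settings$t_end,
    truth = rep(dr$I_final, each = replicates))
  noise <- if (noise_sd == 0) 0 else .with_seed(seed, {
    sd_vec <- if (noise_type == "fraction") noise_sd * abs(rows$truth)
              else noise_sd
    stats::rnorm(nrow(rows), 0, sd_vec)
  })
  rows$reading <- rows$truth + noise
  rows$truth <- NULL
  .new_plate(rows, params, noise_sd, noise_type, seed, mode,
             kind = "dose_response")
}

#' Generate synthetic luminescence time-course data
#'
#' Simulates one biosensor trajectory and returns noisy observations of
#' cumulative luminescence at the requested sampling times, with the
#' ground truth in the attributes. Noise is additive Gaussian, seeded,
#' and independent across rows; negative readings are kept and flagged.
#'
#' @param params A [biosensor_params()] object (`NULL` = reference set).
#' @param init_state Initial biosensor state; `NULL` gives free ABA at
#'   `aba_initial` and everything else zero.
#' @param aba_initial Initial free-ABA level, µM (used when `init_state`
#'   is `NULL`).
#' @param sample_times Strictly increasing observation times, s (>= 2
#'   points unless a single time is truly wanted; `0` is allowed).
#' @param replicates Replicates per time point.
#' @param noise_sd,noise_type,seed,mode As in
#'   [generate_dose_response_data()].
#' @param settings [solver_settings()] for integrator tolerances.
#'
#' @return A `synthetic_plate` with columns `aba_initial`, `replicate`,
#'   `time`, `reading`, `flagged_negative`.
#' @export
generate_trajectory_data <- function(params = NULL, init_state = NULL,
                                     aba_initial = 1.5,
                                     sample_times, replicates = 1,
                                     noise_sd = 0, seed = 1,
                                     settings = solver_settings(),
                                     mode = "mass_action",
                                     noise_type = c("absolute",
                                                    "fraction")) {
  noise_type <- match.arg(noise_type)
  stopifnot(replicates >= 1, noise_sd >= 0)
  tt <- as.numeric(sample_times)
  if (length(tt) < 1L || anyNA(tt) || any(tt < 0) ||
      is.unsorted(tt, strictly = TRUE)) {
    stop("sample_times must be strictly increasing and >= 0",
         call. = FALSE)
  }
  params <- .as_params(if (is.null(params)) biosensor_params() else params,
                       "biosensor_params", biosensor_params)
  if (is.null(init_state)) {
    init_state <- c(C_ABA = aba_initial, mRNA = 0, Protein = 0,
                    Complex = 0, I_biolum = 0)
  }
  y0 <- .check_state(init_state, .BIOSENSOR_STATES)
  times <- unique(c(0, tt))
  sol <- .lsoda_compiled(.model_info("biosensor"), params, mode, y0,
                         times, settings)
  .check_solution(sol, times, "biosensor")
  truth <- sol[match(tt, sol[, 1L]), 6L]
  rows <- data.frame(
    aba_initial = y0[1L],
    replicate = rep(seq_len(replicates), times = length(tt)),
    time = rep(tt, each = replicates),
    truth = rep(truth, each = replicates))
  noise <- if (noise_sd == 0) 0 else .with_seed(seed, {
    sd_vec <- if (noise_type == "fraction") noise_sd * abs(rows$truth)
              else noise_sd
    stats::rnorm(nrow(rows), 0, sd_vec)
  })
  rows$reading <- rows$truth + noise
  rows$truth <- NULL
  .new_plate(rows, params, noise_sd, noise_type, seed, mode,
             kind = "trajectory")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf(
    "Synthetic %s plate: %d readings, noise_sd = %g (%s), seed = %s, %s kinetics\n",
    attr(x, "kind"), nrow(x), attr(x, "noise_sd"), attr(x, "noise_type"),
    format(attr(x, "seed")), attr(x, "mode")))
  if (any(x$flagged_negative)) {
    cat(sprintf("  %d negative readings kept (not clipped)\n",
                sum(x$flagged_negative)))
  }
  print(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
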