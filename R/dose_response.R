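#' Default ABA dose levels for biosensor sweeps
#'
#' Twelve log-spaced initial ABA concentrations spanning 1.5 to 50 µM,
#' the concentration window over which the biosensor model is exercised.
#'
#' @param n Number of levels.
#' @param from,to Range endpoints, µM.
#' @return Strictly increasing numeric vector, µM.
#' @export
default_aba_levels <- function(n = 12, from = 1.5, to = 50) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Dose-response sweep of the biosensor model over initial ABA
#'
#' For each initial ABA concentration, integrates the biosensor model from
#' the standard initial condition — all of `mRNA`, `Protein`, `Complex`
#' and `I_biolum` at zero, free ABA at the given level — and records the
#' final cumulative bioluminescence `I_biolum(t_end)`.
#'
#' @param aba_levels Strictly increasing, nonnegative initial ABA
#'   concentrations, µM. Default: [default_aba_levels()].
#' @param params A [biosensor_params()] object (`NULL` = reference set).
#' @param settings A [solver_settings()] object; `t_end` is the sweep
#'   readout time (default here 3600 s).
#' @param mode Binding-kinetics mode, `"mass_action"` or `"literal"`.
#'
#' @return A `dose_response_table`: data frame with columns `aba_initial`
#'   (µM), `I_final` (RLU) and `converged` (logical, steady by `t_end` per
#'   the settings' `steady_tol`), with attributes `t_end`, `mode` and
#'   `params_digest`.
#'
#' @examples
#' dr <- dose_response(settings = solver_settings(t_end = 600))
#' dr
#' @export
dose_response <- function(aba_levels = default_aba_levels(),
                          params = NULL,
                          settings = solver_settings(t_end = 3600),
                          mode = "mass_action") {
  if (length(aba_levels) == 0L || anyNA(aba_levels) ||
      any(!is.finite(aba_levels)) || any(aba_levels < 0)) {
    stop("aba_levels must be nonempty, finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(aba_levels, strictly = TRUE)) {
    stop("aba_levels must be strictly increasing (no duplicates)",
         call. = FALSE)
  }
  params <- .as_params(if (is.null(params)) biosensor_params() else params,
                       "biosensor_params", biosensor_params)
  info <- .model_info("biosensor")
  out <- lapply(seq_along(aba_levels), function(i) {
    init <- c(C_ABA = aba_levels[i], mRNA = 0, Protein = 0, Complex = 0,
              I_biolum = 0)
    tr <- tryCatch(
      integrate_model("biosensor", params, init, settings, mode),
      error = function(e) {
        stop(sprintf("dose_response failed at level %g µM: %s",
                     aba_levels[i], conditionMessage(e)), call. = FALSE)
      })
    final <- tr$states[nrow(tr$states), ]
    d <- info$rhs(final, params, mode)
    conv <- max(abs(d) / (1 + abs(final))) < settings$steady_tol
    c(I_final = final[5L], converged = conv)
  })
  tab <- data.frame(aba_initial = aba_levels,
                    I_final = vapply(out, `[[`, numeric(1), 1L),
                    converged = as.logical(vapply(out, `[[`, numeric(1), 2L)))
  structure(tab,
            t_end = settings$t_end, mode = mode,
            params_digest = params_digest(params), params = params,
            class = c("dose_response_table", "data.frame"))
}

#' @export
print.dose_response_table <- function(x, ...) {
  cat(sprintf(
    "Biosensor dose-response sweep (%s kinetics, readout at t = %g s)\n",
    attr(x, "mode"), attr(x, "t_end")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Plot a dose-response table
#'
#' Final cumulative luminescence against initial ABA concentration.
#'
#' @param x A `dose_response_table`.
#' @param log Axis log specification passed to [graphics::plot()]
#'   (default `"x"`).
#' @param ... Further plotting arguments.
#' @export
plot.dose_response_table <- function(x, log = "x", ...) {
  graphics::plot(x$aba_initial, x$I_final, log = log, type = "b", pch = 16,
                 xlab = "initial ABA (µM)",
                 ylab = "cumulative luminescence (RLU)",
                 main = "Biosensor dose-response", ...)
  invisible(x)
}
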