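#' Solver settings for model integration
#'
#' @param rel_tol Relative tolerance of the adaptive integrator.
#' @param abs_tol Absolute tolerance of the adaptive integrator. In
#'   `mass_action` biosensor runs, states are also required to stay above
#'   `-abs_tol`; a larger excursion aborts with a diagnostic.
#' @param t_end Integration horizon, s.
#' @param max_step Optional maximal internal step, s (`Inf` = unlimited).
#' @param steady_tol Steady-state threshold on the normalized derivative
#'   norm `max |dy/dt| / (1 + |y|)` used by [run_to_steady()].
#' @param n_report Number of evenly spaced output time points (>= 2).
#'
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10, t_end = 100,
                            max_step = Inf, steady_tol = 1e-9,
                            n_report = 200) {
  stopifnot(is.numeric(rel_tol), rel_tol > 0,
            is.numeric(abs_tol), abs_tol > 0,
            is.numeric(t_end), is.finite(t_end), t_end > 0,
            is.numeric(max_step), max_step > 0,
            is.numeric(steady_tol), steady_tol > 0,
            is.numeric(n_report), n_report >= 2)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, t_end = t_end,
                 max_step = max_step, steady_tol = steady_tol,
                 n_report = as.integer(n_report)),
            class = "solver_settings")
}

.prep_run <- function(model_id, params, init_state, mode) {
  info <- .model_info(model_id)
  params <- if (is.null(params)) info$ctor() else
    .as_params(params, info$param_class, info$ctor)
  y0 <- if (is.null(init_state)) unname(info$default_init) else
    .check_state(init_state, info$states)
  if (info$needs_mode) .check_kinetics_mode(mode)
  list(info = info, params = params, y0 = y0, mode = mode)
}

.new_trajectory <- function(times, states, model_id, mode, params, info) {
  colnames(states) <- info$states
  structure(list(times = times, states = states, model_id = model_id,
                 mode = if (info$needs_mode) mode else NA_character_,
                 params = params, params_digest = params_digest(params)),
            class = "aba_trajectory")
}

#' Integrate a model with an adaptive stiff-capable solver
#'
#' Runs the chosen model from an initial state over `[0, t_end]` using
#' `deSolve`'s LSODA method (adaptive step, automatic stiff/non-stiff
#' switching) at the tolerances in `settings`, reporting the solution on
#' an evenly spaced grid of `n_report` points.
#'
#' @param model_id One of `"signaling_aba"`, `"signaling_noaba"`,
#'   `"biosensor"`.
#' @param params Parameter object matching the model
#'   ([signaling_params()] or [biosensor_params()]); `NULL` for the model's
#'   reference set.
#' @param init_state Named initial state (µM; RLU for `I_biolum`); `NULL`
#'   for the model's documented default.
#' @param settings A [solver_settings()] object.
#' @param mode Binding-kinetics interpretation for the biosensor model
#'   (`"mass_action"` or `"literal"`); ignored by the signaling models.
#'
#' @return An `aba_trajectory`: list with `times`, a `states` matrix (one
#'   row per time point, columns in the model's documented order), the
#'   `model_id`, `mode`, `params` and a `params_digest` provenance string.
#'   The first row equals the initial state exactly.
#'
#' @examples
#' tr <- integrate_model("biosensor",
#'                       settings = solver_settings(t_end = 600))
#' tail(as.data.frame(tr), 2)
#' @export
integrate_model <- function(model_id, params = NULL, init_state = NULL,
                            settings = solver_settings(),
                            mode = "mass_action") {
  run <- .prep_run(model_id, params, init_state, mode)
  times <- seq(0, settings$t_end, length.out = settings$n_report)
  sol <- .lsoda_compiled(run$info, run$params, mode, run$y0, times,
                         settings)
  .check_solution(sol, times, model_id)
  states <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  states[1L, ] <- run$y0  # exact initial state, untouched by the solver
  if (model_id == "biosensor" && mode == "mass_action") {
    .check_nonneg(states, times, settings$abs_tol)
  }
  .new_trajectory(times, states, model_id, mode, run$params, run$info)
}

# All adaptive integrations go through the package's compiled RHS
# (src/abasim_rhs.c); the R-level RHS functions stay the reference
# definitions used by rk4_reference(), so oracle tests cross-check the
# two implementations.
.lsoda_compiled <- function(info, params, mode, y0, times, settings) {
  if (length(times) < 2L) {
    return(matrix(c(times, y0), nrow = 1L))
  }
  deSolve::lsoda(y = y0, times = times, func = info$c_func,
                 dllname = "abasim", initfunc = info$c_init,
                 parms = info$c_parms(params, mode),
                 rtol = settings$rel_tol, atol = settings$abs_tol,
                 hmax = if (is.finite(settings$max_step))
                   settings$max_step else NULL)
}

.check_solution <- function(sol, times, model_id) {
  if (nrow(sol) < length(times) || anyNA(sol) || any(!is.finite(sol))) {
    t_fail <- if (nrow(sol) >= 1L) sol[nrow(sol), 1L] else 0
    stop(sprintf("integration of '%s' failed near t = %g s", model_id,
                 t_fail), call. = FALSE)
  }
  invisible(sol)
}

.check_nonneg <- function(states, times, abs_tol) {
  # concentration columns only; cumulative light is checked elsewhere
  low <- apply(states, 1L, min)
  bad <- which(low < -abs_tol)
  if (length(bad)) {
    stop(sprintf(
      "mass-action state fell below -abs_tol (min %.3g at t = %g s)",
      low[bad[1L]], times[bad[1L]]), call. = FALSE)
  }
  invisible(states)
}

#' Fixed-step classical Runge-Kutta reference integration
#'
#' Integrates the same right-hand sides as [integrate_model()] with the
#' classical 4th-order Runge-Kutta scheme at a fixed step, as an
#' independent oracle for cross-validating the adaptive solver. Between
#' consecutive output times the interval is covered by equal substeps of
#' size at most `dt`, so every output time is hit exactly and the scheme
#' remains deterministic. Global error scales as `dt^4`.
#'
#' @inheritParams integrate_model
#' @param dt Fixed step size, s (> 0; at most 1e7 steps overall).
#' @param t_end Horizon, s.
#' @param n_report Number of evenly spaced output points.
#'
#' @return An `aba_trajectory` (same shape as [integrate_model()]).
#' @export
rk4_reference <- function(model_id, params = NULL, init_state = NULL,
                          dt, t_end, mode = "mass_action",
                          n_report = 200) {
  stopifnot(is.numeric(dt), dt > 0, is.numeric(t_end), t_end > 0)
  if (t_end / dt > 1e7) {
    stop("rk4_reference(): t_end/dt exceeds 1e7 steps", call. = FALSE)
  }
  run <- .prep_run(model_id, params, init_state, mode)
  rhs <- run$info$rhs
  p <- run$params
  times <- seq(0, t_end, length.out = n_report)
  states <- matrix(NA_real_, nrow = length(times), ncol = length(run$y0))
  y <- run$y0
  states[1L, ] <- y
  for (i in seq_len(length(times) - 1L)) {
    span <- times[i + 1L] - times[i]
    nsub <- max(1L, ceiling(span / dt - 1e-9))
    h <- span / nsub
    for (s in seq_len(nsub)) {
      k1 <- rhs(y, p, mode)
      k2 <- rhs(y + h / 2 * k1, p, mode)
      k3 <- rhs(y + h / 2 * k2, p, mode)
      k4 <- rhs(y + h * k3, p, mode)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (anyNA(y) || any(!is.finite(y))) {
        stop(sprintf("rk4_reference(): non-finite state near t = %g s",
                     times[i] + s * h), call. = FALSE)
      }
    }
    states[i + 1L, ] <- y
  }
  .new_trajectory(times, states, model_id, mode, p, run$info)
}

#' Run a model to (approximate) steady state
#'
#' Integrates until the normalized derivative norm
#' `max_i |dy_i/dt| / (1 + |y_i|)` drops below `settings$steady_tol`, or
#' until `settings$t_end`. Convergence is checked at the initial state and
#' then on a dense monitoring grid.
#'
#' @inheritParams integrate_model
#'
#' @return A list with `state` (named), `converged` (logical), and
#'   `t_reached` (s): the first monitored time at which the criterion held,
#'   or `t_end` with `converged = FALSE`.
#'
#' @examples
#' p <- biosensor_params(k_prod = 0.05, k_deg = 0.025)
#' st <- run_to_steady("biosensor", p,
#'                     init_state = c(C_ABA = 0, mRNA = 0, Protein = 0,
#'                                    Complex = 0, I_biolum = 0),
#'                     settings = solver_settings(t_end = 2000))
#' st$state[["C_ABA"]]   # k_prod / k_deg = 2
#' @export
run_to_steady <- function(model_id, params = NULL, init_state = NULL,
                          settings = solver_settings(),
                          mode = "mass_action") {
  run <- .prep_run(model_id, params, init_state, mode)
  rhs <- run$info$rhs
  crit <- function(y) {
    d <- rhs(y, run$params, mode)
    max(abs(d) / (1 + abs(y)))
  }
  if (crit(run$y0) < settings$steady_tol) {
    st <- run$y0
    names(st) <- run$info$states
    return(list(state = st, converged = TRUE, t_reached = 0))
  }
  n_mon <- max(settings$n_report, 400L)
  tr <- integrate_model(model_id, run$params, run$y0,
                        settings = solver_settings(
                          rel_tol = settings$rel_tol,
                          abs_tol = settings$abs_tol,
                          t_end = settings$t_end,
                          max_step = settings$max_step,
                          steady_tol = settings$steady_tol,
                          n_report = n_mon),
                        mode = mode)
  norms <- apply(tr$states, 1L, crit)
  hit <- which(norms < settings$steady_tol)
  if (length(hit)) {
    i <- hit[1L]
    st <- tr$states[i, ]
    names(st) <- run$info$states
    list(state = st, converged = TRUE, t_reached = tr$times[i])
  } else {
    st <- tr$states[nrow(tr$states), ]
    names(st) <- run$info$states
    list(state = st, converged = FALSE, t_reached = settings$t_end)
  }
}

#' @export
print.aba_trajectory <- function(x, ...) {
  cat(sprintf("<aba_trajectory> model '%s'%s, %d time points over [0, %g] s\n",
              x$model_id,
              if (!is.na(x$mode)) sprintf(" (%s kinetics)", x$mode) else "",
              length(x$times), max(x$times)))
  cat("final state:\n")
  print(stats::setNames(x$states[nrow(x$states), ], colnames(x$states)))
  invisible(x)
}

#' @export
as.data.frame.aba_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$states, check.names = FALSE)
}

#' Plot a trajectory
#'
#' One line per state variable against time, on a shared linear axis.
#'
#' @param x An `aba_trajectory`.
#' @param vars Optional subset of state-variable names to draw.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.aba_trajectory <- function(x, vars = NULL, ...) {
  states <- x$states
  if (!is.null(vars)) states <- states[, vars, drop = FALSE]
  graphics::matplot(x$times, states, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "level (µM / au / RLU)",
                    main = sprintf("%s trajectory", x$model_id), ...)
  graphics::legend("topleft", legend = colnames(states), lty = 1,
                   col = seq_len(ncol(states)), bty = "n")
  invisible(x)
}
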