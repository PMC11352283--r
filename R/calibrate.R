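#' Calibrate biosensor parameters against luminescence readings
#'
#' Nonlinear least-squares estimation of selected biosensor parameters
#' from endpoint or time-course relative-light-unit (RLU) readings. For
#' every distinct initial ABA level in the data, the forward model
#' integrates the biosensor ODE system from the standard initial
#' condition (free ABA at the level, everything else zero) and evaluates
#' cumulative `I_biolum` at the observed times; the residuals
#' `reading - I_model` are minimised by bounded Levenberg-Marquardt in
#' log-parameter space, from several multistart points drawn log-uniform
#' within the bounds (seeded, so fits are reproducible).
#'
#' @param data Data frame with columns `aba_initial` (µM), `time` (s) and
#'   `reading` (RLU); optional columns `replicate` and `weight`
#'   (per-point least-squares weights). A [generate_dose_response_data()]
#'   or [generate_trajectory_data()] plate works directly.
#' @param free_params Named list of `c(lower, upper)` bounds, one entry
#'   per parameter to estimate, e.g.
#'   `list(K_half = c(0.05, 20), k_response = c(0.01, 100))`. Bounds must
#'   be finite and strictly positive.
#' @param fixed_params A [biosensor_params()] object (or argument list)
#'   supplying every non-estimated parameter; `NULL` = reference set.
#' @param settings [solver_settings()] controlling the forward
#'   integrations (tolerances; `t_end` is taken from the data's largest
#'   observation time).
#' @param mode Biosensor kinetics mode.
#' @param seed Integer seed for the multistart draw.
#' @param n_starts Number of multistart points (default 8; the bound
#'   midpoint in log space is always included).
#'
#' @return An object of class `biosensor_fit`: `estimates` (named,
#'   natural units), `rss`, `converged`, `n_iterations` (of the winning
#'   start), `seed`, `bound_active` (names of estimates pinned at a
#'   bound), `starts` (per-start summary), plus data and metadata.
#'   Methods: `print`, `coef`, `summary`, `predict` (model readings for a
#'   data frame of `aba_initial`/`time`), `residuals`.
#' @seealso [generate_dose_response_data()] for synthetic calibration data
#' @export
fit_biosensor_params <- function(data, free_params, fixed_params = NULL,
                                 settings = solver_settings(rel_tol = 1e-6,
                                                            abs_tol = 1e-8),
                                 mode = "mass_action", seed = 0,
                                 n_starts = 8) {
  if (!is.data.frame(data) ||
      !all(c("aba_initial", "time", "reading") %in% names(data))) {
    stop("data must contain columns aba_initial, time, reading",
         call. = FALSE)
  }
  if (!is.list(free_params) || is.null(names(free_params)) ||
      any(!nzchar(names(free_params)))) {
    stop("free_params must be a named list of c(lower, upper) bounds",
         call. = FALSE)
  }
  fixed <- .as_params(if (is.null(fixed_params)) biosensor_params()
                      else fixed_params,
                      "biosensor_params", biosensor_params)
  bad <- setdiff(names(free_params), names(fixed))
  if (length(bad)) {
    stop("unknown biosensor parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bounds <- do.call(rbind, free_params)
  if (!is.numeric(bounds) || ncol(bounds) != 2L || anyNA(bounds) ||
      any(!is.finite(bounds)) || any(bounds <= 0) ||
      any(bounds[, 1L] >= bounds[, 2L])) {
    stop("each free_params entry must be finite positive c(lower, upper) with lower < upper",
         call. = FALSE)
  }
  n_free <- length(free_params)
  if (nrow(data) < n_free) {
    stop("fewer data points than free parameters", call. = FALSE)
  }
  w <- if ("weight" %in% names(data)) sqrt(data$weight) else
    rep(1, nrow(data))

  # one forward solve per dose, evaluated at that dose's observed times
  by_dose <- split(seq_len(nrow(data)), data$aba_initial)
  levels <- as.numeric(names(by_dose))
  binfo <- .model_info("biosensor")
  fwd <- function(theta) {
    p <- fixed
    shared_K <- p$K_half == p$K_half_response &&
      !"K_half_response" %in% names(free_params)
    for (i in seq_len(n_free)) p[[names(free_params)[i]]] <- theta[i]
    if (shared_K && "K_half" %in% names(free_params)) {
      p$K_half_response <- p$K_half
    }
    pred <- numeric(nrow(data))
    for (j in seq_along(by_dose)) {
      idx <- by_dose[[j]]
      tt <- sort(unique(data$time[idx]))
      times <- unique(c(0, tt))
      init <- c(levels[j], 0, 0, 0, 0)
      sol <- .lsoda_compiled(binfo, p, mode, init, times, settings)
      if (nrow(sol) < length(times) || anyNA(sol)) {
        return(rep(NA_real_, nrow(data)))
      }
      I_at <- sol[match(data$time[idx], sol[, 1L]), 6L]
      pred[idx] <- I_at
    }
    pred
  }
  resid_fn <- function(logtheta) {
    pred <- fwd(exp(logtheta))
    if (anyNA(pred)) return(rep(1e6, nrow(data)))
    w * (data$reading - pred)
  }

  llo <- log(bounds[, 1L]); lhi <- log(bounds[, 2L])
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- rbind((llo + lhi) / 2,
                  matrix(stats::runif((n_starts - 1L) * n_free),
                         ncol = n_free) %*% diag(lhi - llo, n_free) +
                    matrix(llo, n_starts - 1L, n_free, byrow = TRUE))
  best <- NULL
  start_log <- data.frame(start = integer(), rss = numeric(),
                          converged = logical())
  for (s in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = llo, upper = lhi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    conv <- !is.null(f) && f$info %in% 1:4
    start_log <- rbind(start_log,
                       data.frame(start = s,
                                  rss = if (is.null(f)) NA_real_
                                        else f$deviance,
                                  converged = conv))
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) {
      best <- f
    }
  }
  if (is.null(best)) {
    stop("fit_biosensor_params(): no multistart run converged",
         call. = FALSE)
  }
  est <- exp(best$par)
  names(est) <- names(free_params)
  at_bound <- names(est)[est <= bounds[, 1L] * (1 + 1e-6) |
                           est >= bounds[, 2L] * (1 - 1e-6)]
  structure(list(estimates = est, rss = best$deviance,
                 converged = best$info %in% 1:4 && !length(at_bound),
                 bound_active = at_bound,
                 n_iterations = best$niter, seed = seed,
                 starts = start_log, bounds = bounds,
                 fixed_params = fixed, mode = mode,
                 data = data, fitted = fwd(est),
                 params_digest = params_digest(fixed)),
            class = "biosensor_fit")
}

#' @export
print.biosensor_fit <- function(x, ...) {
  cat(sprintf("Biosensor calibration (%s kinetics, %d points, seed %s)\n",
              x$mode, nrow(x$data), format(x$seed)))
  print(signif(x$estimates, 6))
  cat(sprintf("RSS %.6g after %d LM iterations; converged: %s\n",
              x$rss, x$n_iterations, x$converged))
  if (length(x$bound_active)) {
    cat("estimates at a bound:", paste(x$bound_active, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
coef.biosensor_fit <- function(object, ...) object$estimates

#' @export
residuals.biosensor_fit <- function(object, ...) {
  object$data$reading - object$fitted
}

#' @export
summary.biosensor_fit <- function(object, ...) {
  print(object)
  cat("multistart RSS values:\n")
  print(object$starts, row.names = FALSE)
  invisible(object)
}

#' @export
predict.biosensor_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  p <- object$fixed_params
  for (nm in names(object$estimates)) p[[nm]] <- object$estimates[[nm]]
  if (!"K_half_response" %in% names(object$estimates) &&
      "K_half" %in% names(object$estimates)) {
    p$K_half_response <- p$K_half
  }
  binfo <- .model_info("biosensor")
  vapply(seq_len(nrow(newdata)), function(i) {
    sol <- .lsoda_compiled(binfo, p, object$mode,
                           c(newdata$aba_initial[i], 0, 0, 0, 0),
                           unique(c(0, newdata$time[i])),
                           solver_settings(t_end = max(newdata$time[i],
                                                       1e-9)))
    sol[nrow(sol), 6L]
  }, numeric(1))
}
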