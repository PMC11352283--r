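#' Fit a Hill curve to dose-response data
#'
#' Least-squares fit of the three-parameter Hill model
#' \deqn{y = top \cdot \frac{C^n}{K_{half}^n + C^n}}
#' to `(dose, response)` pairs, by Levenberg-Marquardt with box
#' constraints keeping `top >= 0`, `K_half > 0` and `n > 0`. Several
#' starting points (heuristic `K_half` from the half-maximal dose;
#' `n` in 0.5, 1, 2, 4) are tried and the best fit kept, so the routine
#' is robust to the strong `K_half`-`n` coupling of Hill fits.
#'
#' @param doses Dose levels, µM; at least 4 distinct values.
#' @param responses Responses, RLU; finite, with nonzero range.
#'
#' @return An object of class `hill_fit`: coefficients `top` (RLU),
#'   `K_half` (µM), `n` (dimensionless), plus `rss`, `r2`, `fitted`,
#'   `residuals` and the data. Methods: `print`, `summary`, `coef`,
#'   `predict(object, newdata = <doses>)`, `residuals`, `plot`.
#'
#' @examples
#' d <- default_aba_levels(12, 0.1, 100)
#' y <- 48 * d^2 / (5^2 + d^2)
#' coef(fit_hill(d, y))
#' @export
fit_hill <- function(doses, responses) {
  x <- as.numeric(doses)
  y <- as.numeric(responses)
  if (length(x) != length(y)) {
    stop("doses and responses must have equal length", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("doses must be finite and >= 0", call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop("responses must be finite", call. = FALSE)
  }
  if (length(unique(x)) < 4L) {
    stop("fit_hill() needs at least 4 distinct dose levels", call. = FALSE)
  }
  rng <- diff(range(y))
  if (rng <= 8 * .Machine$double.eps * max(abs(y), 1e-300)) {
    stop("degenerate data: response range is at machine scale of its magnitude",
         call. = FALSE)
  }

  obj <- function(par) y - par[1L] * .hill_raw_vec(x, par[2L], par[3L])
  # heuristic K_half: dose closest to half-maximal response
  K0 <- x[which.min(abs(y - (min(y) + rng / 2)))]
  if (K0 <= 0) K0 <- stats::median(x[x > 0])
  starts <- lapply(c(0.5, 1, 2, 4),
                   function(n0) c(max(y) * 1.05, K0, n0))
  lower <- c(0, 1e-9, 1e-9)
  upper <- c(Inf, Inf, 1e3)
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = obj,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) {
      best <- f
    }
  }
  if (is.null(best)) {
    stop("fit_hill() failed to converge from any starting point",
         call. = FALSE)
  }
  par <- best$par
  fitted <- par[1L] * .hill_raw_vec(x, par[2L], par[3L])
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = c(top = par[1L], K_half = par[2L],
                                  n = par[3L]),
                 rss = rss, r2 = max(0, min(1, 1 - rss / tss)),
                 fitted = fitted, residuals = y - fitted,
                 doses = x, responses = y,
                 niter = best$niter,
                 message = best$message),
            class = "hill_fit")
}

.hill_raw_vec <- function(C, K_half, n) {
  r <- (C / K_half)^n
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill-curve fit: y = top * C^n / (K_half^n + C^n)\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("RSS %.6g, R² %.6f on %d points\n", x$rss, x$r2,
              length(x$doses)))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  cat(sprintf("residual range: [%.3g, %.3g]\n", min(object$residuals),
              max(object$residuals)))
  invisible(object)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$doses else as.numeric(newdata)
  cf <- object$coefficients
  cf[["top"]] * .hill_raw_vec(x, cf[["K_half"]], cf[["n"]])
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$doses, x$responses, log = "x", pch = 16,
                 xlab = "dose (µM)", ylab = "response (RLU)",
                 main = "Hill fit", ...)
  grid_x <- exp(seq(log(max(min(x$doses), 1e-3)), log(max(x$doses)),
                    length.out = 200))
  graphics::lines(grid_x, predict(x, grid_x), col = 2)
  invisible(x)
}

#' Linearity of a dose-response sweep
#'
#' Ordinary least-squares line of final luminescence on initial ABA
#' concentration, summarising how close a sweep is to the proportional
#' regime in which the biosensor is a linear ABA meter.
#'
#' @param table A `dose_response_table` (or any data frame with columns
#'   `aba_initial` and `I_final`), with at least 3 rows.
#'
#' @return An object of class `linear_fit`: `slope` (RLU/µM), `intercept`
#'   (RLU) and `r2`. For zero-variance responses the slope is 0 and `r2`
#'   is defined as 0, with a warning.
#' @export
linearity_check <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("aba_initial", "I_final") %in% names(table))) {
    stop("linearity_check() expects a dose_response_table (columns aba_initial, I_final)",
         call. = FALSE)
  }
  if (nrow(table) < 3L) {
    stop("linearity_check() needs at least 3 dose levels", call. = FALSE)
  }
  x <- table$aba_initial
  y <- table$I_final
  if (stats::var(y) == 0) {
    warning("responses have zero variance; r2 defined as 0", call. = FALSE)
    fit <- list(slope = 0, intercept = y[1L], r2 = 0)
  } else {
    m <- stats::lm(y ~ x)
    r2 <- 1 - sum(stats::residuals(m)^2) / sum((y - mean(y))^2)
    fit <- list(slope = unname(stats::coef(m)[2L]),
                intercept = unname(stats::coef(m)[1L]),
                r2 = r2)
  }
  structure(fit, class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "Linear fit: I_final = %.6g + %.6g * ABA (RLU), R² = %.4f\n",
    x$intercept, x$slope, x$r2))
  invisible(x)
}
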