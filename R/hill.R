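#' Hill function for cooperative ligand binding
#'
#' Fractional occupancy of a receptor by a ligand at concentration `C`,
#' assuming cooperative binding with Hill coefficient `n` and half-maximal
#' concentration `K_half`:
#' \deqn{f(C) = \frac{C^n}{K_{half}^n + C^n}}
#' The value lies in `[0, 1)`, is strictly increasing in `C`, equals 0.5 at
#' `C = K_half` for every `n`, and tends to 1 as `C` grows.
#'
#' @param C Ligand concentration, µM. Nonnegative; vectorised.
#' @param K_half Half-maximal concentration, µM. Strictly positive.
#' @param n Hill coefficient (cooperativity), dimensionless. Strictly
#'   positive; `n = 1` gives simple hyperbolic (Michaelis-Menten-like)
#'   binding.
#'
#' @return Numeric vector of occupancies, same length as `C`.
#'
#' @examples
#' hill(2, K_half = 2, n = 3)   # 0.5 at the half-maximal point
#' hill(3, K_half = 1, n = 1)   # 3/4
#' @export
hill <- function(C, K_half, n) {
  if (!is.numeric(C) || anyNA(C) || any(!is.finite(C)) || any(C < 0)) {
    stop("hill(): 'C' must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(K_half) || length(K_half) != 1L || !is.finite(K_half) ||
      K_half <= 0) {
    stop("hill(): 'K_half' must be a finite scalar > 0", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("hill(): 'n' must be a finite scalar > 0", call. = FALSE)
  }
  # (C/K)^n form avoids overflow for large C or n
  r <- (C / K_half)^n
  ifelse(is.infinite(r), 1, r / (1 + r))
}

# Unchecked scalar/vector core for use inside RHS hot loops.
.hill_raw <- function(C, K_half, n) {
  r <- (C / K_half)^n
  if (is.infinite(r)) 1 else r / (1 + r)
}
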