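#' Parameter set for the ABA signaling models
#'
#' Bundles every rate constant of the SnRK2/PP2C/MAPK signaling models, in
#' the package's unit convention (concentrations in µM, time in seconds).
#' The ABA-present model uses all fields; the ABA-free model uses only the
#' three protein-interaction rates.
#'
#' Defaults are the package's reference signaling set, chosen as generic
#' order-one rates for a µM/second system (the models' qualitative behavior
#' — SnRK2 activation with ABA, SnRK2 deactivation by PP2C without — does
#' not depend on the particular values).
#'
#' @param k_synthesis ABA production rate, µM/s.
#' @param K1 First-order ABA loss rate, 1/s.
#' @param K2 SnRK2 activation scale multiplying the ABA Hill occupancy,
#'   µM/s.
#' @param K3 Direct ABA-to-MAPK coupling rate, 1/s.
#' @param k_interact_SNRK2 SnRK2-driven interaction rate, 1/s.
#' @param k_interact_PP2C PP2C turnover rate, 1/s.
#' @param k_interact_MAPK PP2C-to-MAPK (and PP2C-on-SnRK2) interaction
#'   rate, 1/s.
#' @param K_half Half-maximal ABA concentration of the receptor Hill term,
#'   µM.
#' @param n Hill coefficient, dimensionless.
#'
#' @return An object of class `signaling_params` (named list).
#' @seealso [signaling_rhs_with_aba()], [signaling_rhs_without_aba()]
#' @export
signaling_params <- function(k_synthesis = 1.0, K1 = 0.5, K2 = 2.0,
                             K3 = 0.1, k_interact_SNRK2 = 0.3,
                             k_interact_PP2C = 0.2, k_interact_MAPK = 0.4,
                             K_half = 1.0, n = 2.0) {
  p <- list(k_synthesis = k_synthesis, K1 = K1, K2 = K2, K3 = K3,
            k_interact_SNRK2 = k_interact_SNRK2,
            k_interact_PP2C = k_interact_PP2C,
            k_interact_MAPK = k_interact_MAPK,
            K_half = K_half, n = n)
  .check_rates(p, positive = c("K_half", "n"))
  structure(p, class = "signaling_params")
}

#' Parameter set for the bioluminescent ABA biosensor model
#'
#' Rate constants of the whole-cell biosensor model: free-ABA turnover,
#' ABA-receptor association/dissociation, reporter mRNA transcription
#' driven by a Hill term in free ABA, translation, protein turnover, and a
#' cumulative luminescence response driven by a Hill term in the
#' ABA-protein complex.
#'
#' Units: concentrations in µM, time in seconds, luminescence in relative
#' light units (RLU; the scale is set by `k_response`). The association
#' rate may be given either as `kon` in µM^-1 s^-1 (the internal unit) or
#' as `kon_M` in M^-1 s^-1, the unit in which binding kinetics are usually
#' reported; `kon_M` is converted internally by 1e-6. Plausible ranges for
#' ABA biosensors are kon in 1e4-1e6 M^-1 s^-1 and koff in 1e-4-1e-2 1/s;
#' values outside these ranges trigger a warning, not an error.
#'
#' The defaults are the package's reference biosensor set: kon = 1e5
#' M^-1 s^-1 and koff = 1e-3 1/s (log-midpoints of the plausible ranges),
#' n = 1, K_half = 1 µM, no intrinsic ABA production, slow ABA
#' degradation, and order-0.1 expression rates.
#'
#' @param k_prod ABA production rate, µM/s.
#' @param k_deg Free-ABA degradation rate, 1/s.
#' @param kon Association rate, µM^-1 s^-1. Give at most one of `kon`,
#'   `kon_M`.
#' @param kon_M Association rate in M^-1 s^-1 (converted to µM^-1 s^-1 by
#'   1e-6).
#' @param koff Dissociation rate, 1/s.
#' @param k_trans Maximal mRNA transcription rate, au/s.
#' @param k_tran_deg mRNA degradation rate, 1/s.
#' @param k_tran_syn Translation rate per unit mRNA, µM au^-1 s^-1.
#' @param k_deg_prot Sensor-protein degradation rate, 1/s.
#' @param k_response Luminescence response scale, RLU/s.
#' @param K_half Half-maximal level shared by the transcription Hill term
#'   (µM of free ABA) and the response Hill term (µM of complex).
#' @param K_half_response Optional separate half-maximal level for the
#'   response Hill term, µM of complex. `NULL` (default) shares `K_half`.
#' @param n Hill coefficient for both Hill terms, dimensionless.
#'
#' @return An object of class `biosensor_params` (named list); the stored
#'   `kon` is always in µM^-1 s^-1.
#' @seealso [biosensor_rhs()], [dose_response()]
#' @export
biosensor_params <- function(k_prod = 0, k_deg = 0.01, kon = NULL,
                             kon_M = NULL, koff = 1e-3, k_trans = 0.2,
                             k_tran_deg = 0.1, k_tran_syn = 0.3,
                             k_deg_prot = 0.02, k_response = 1,
                             K_half = 1, K_half_response = NULL, n = 1) {
  if (!is.null(kon) && !is.null(kon_M)) {
    stop("biosensor_params(): give only one of 'kon' (µM⁻¹s⁻¹) and 'kon_M' (M⁻¹s⁻¹)",
         call. = FALSE)
  }
  if (!is.null(kon_M) && (!is.numeric(kon_M) || length(kon_M) != 1L ||
                          !is.finite(kon_M))) {
    stop("parameter 'kon_M' must be a finite numeric scalar",
         call. = FALSE)
  }
  if (is.null(kon)) {
    kon <- if (is.null(kon_M)) 0.1 else kon_M / 1e6
  }
  p <- list(k_prod = k_prod, k_deg = k_deg, kon = kon, koff = koff,
            k_trans = k_trans, k_tran_deg = k_tran_deg,
            k_tran_syn = k_tran_syn, k_deg_prot = k_deg_prot,
            k_response = k_response, K_half = K_half,
            K_half_response = if (is.null(K_half_response)) K_half
                              else K_half_response,
            n = n)
  .check_rates(p, positive = c("K_half", "K_half_response", "n"))
  kon_in_M <- p$kon * 1e6
  if (kon_in_M != 0 && (kon_in_M < 1e4 || kon_in_M > 1e6)) {
    warning(sprintf(
      "kon = %.3g M⁻¹s⁻¹ lies outside the plausible ABA-biosensor range [1e4, 1e6]",
      kon_in_M), call. = FALSE)
  }
  if (p$koff != 0 && (p$koff < 1e-4 || p$koff > 1e-2)) {
    warning(sprintf(
      "koff = %.3g s⁻¹ lies outside the plausible ABA-biosensor range [1e-4, 1e-2]",
      p$koff), call. = FALSE)
  }
  structure(p, class = "biosensor_params")
}

# All entries finite and >= 0; entries named in `positive` must be > 0.
.check_rates <- function(p, positive = character()) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a finite numeric scalar", nm),
           call. = FALSE)
    }
    lo_ok <- if (nm %in% positive) v > 0 else v >= 0
    if (!lo_ok) {
      stop(sprintf("parameter '%s' must be %s (got %g)", nm,
                   if (nm %in% positive) "> 0" else ">= 0", v),
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.signaling_params <- function(x, ...) {
  cat("ABA signaling parameters (µM, s):\n")
  .print_params(x)
  invisible(x)
}

#' @export
print.biosensor_params <- function(x, ...) {
  cat("ABA biosensor parameters (µM, s, RLU):\n")
  .print_params(x)
  cat(sprintf("  (kon = %.3g M⁻¹s⁻¹ in molar units)\n", x$kon * 1e6))
  invisible(x)
}

.print_params <- function(x) {
  w <- max(nchar(names(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-*s = %g\n", w, nm, x[[nm]]))
  }
}

.check_kinetics_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L ||
      !mode %in% c("literal", "mass_action")) {
    stop("'mode' must be \"literal\" or \"mass_action\"", call. = FALSE)
  }
  mode
}

# Canonical provenance fingerprint of a parameter set: name=value pairs at
# full precision, order fixed by the constructor.
params_digest <- function(params) {
  paste(sprintf("%s=%.17g", names(params), unlist(params)),
        collapse = ";")
}
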