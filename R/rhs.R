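#' @name signaling_rhs
#' @title Right-hand sides of the ABA signaling models
#'
#' @description
#' Time derivatives (per second) of the SnRK2/PP2C/MAPK signaling system,
#' with and without ABA.
#'
#' With ABA present, the system is
#' \deqn{dC_{ABA}/dt = k_{synthesis} - K_1 C_{ABA}}
#' \deqn{dSnRK2/dt = K_2 \, h(C_{ABA})}
#' \deqn{dPP2C/dt = k_{iS} SnRK2 - k_{iP} PP2C}
#' \deqn{dMAPK/dt = -k_{iS} SnRK2 + k_{iM} PP2C + K_3 C_{ABA}}
#' where \eqn{h} is the Hill occupancy [hill()] with the set's `K_half`
#' and `n`. SnRK2 is nondecreasing (its derivative is a nonnegative Hill
#' term): ABA perception keeps the positive regulator active.
#'
#' Without ABA the system reduces to the protein-protein interactions
#' \deqn{dPP2C/dt = k_{iS} SnRK2 - k_{iP} PP2C}
#' \deqn{dMAPK/dt = -k_{iS} SnRK2 + k_{iM} PP2C}
#' \deqn{dSnRK2/dt = -k_{iM} PP2C}
#' so SnRK2 can only fall while PP2C is nonnegative: the phosphatase
#' deactivates the kinase. The `C_ABA` entry is carried with derivative 0.
#' Note the ABA-free system is linear and, when `k_interact_PP2C = 0`,
#' conserves SnRK2 + PP2C + MAPK.
#'
#' These are the literal printed model equations: SnRK2 grows without
#' bound in the ABA-present model, the ABA-free SnRK2 equation does not
#' depend on SnRK2 itself, and state variables may go negative. Both
#' properties are retained deliberately.
#'
#' @param state Named numeric vector or list with entries `C_ABA`,
#'   `SNRK2`, `PP2C`, `MAPK` (µM). All finite; negative values allowed.
#' @param params A [signaling_params()] object.
#' @return Named numeric vector of derivatives, µM/s, in state order.
NULL

#' @rdname signaling_rhs
#' @examples
#' p <- signaling_params()
#' signaling_rhs_with_aba(c(C_ABA = 1, SNRK2 = 2, PP2C = 1, MAPK = 0.5), p)
#' @export
signaling_rhs_with_aba <- function(state, params) {
  y <- .check_state(state, .SIGNALING_STATES)
  params <- .as_params(params, "signaling_params", signaling_params)
  d <- .rhs_signaling_aba(y, params)
  names(d) <- .SIGNALING_STATES
  d
}

#' @rdname signaling_rhs
#' @export
signaling_rhs_without_aba <- function(state, params) {
  y <- .check_state(state, .SIGNALING_STATES)
  params <- .as_params(params, "signaling_params", signaling_params)
  d <- .rhs_signaling_noaba(y, params)
  names(d) <- .SIGNALING_STATES
  d
}

#' Right-hand side of the bioluminescent biosensor model
#'
#' Time derivatives (per second) of the five-variable biosensor model:
#' free ABA (`C_ABA`, µM), reporter transcript (`mRNA`, au), free sensor
#' protein (`Protein`, µM), ABA-protein complex (`Complex`, µM), and
#' cumulative bioluminescence (`I_biolum`, RLU).
#'
#' In both kinetics modes, transcription follows a Hill term in free ABA,
#' \deqn{dmRNA/dt = k_{trans} h(C_{ABA}) - k_{tran\_deg}\, mRNA,}
#' and luminescence accumulates through a Hill term in the complex,
#' \deqn{dI/dt = k_{response} \, h_r(Complex) \ge 0,}
#' so `I_biolum` is nondecreasing whenever it starts at 0.
#'
#' The binding scheme ABA + Protein <-> Complex is interpreted by `mode`:
#' \describe{
#'   \item{`"mass_action"` (default)}{Physically consistent fluxes:
#'     association \eqn{\phi^+ = k_{on} C_{ABA} Protein}, dissociation
#'     \eqn{\phi^- = k_{off} Complex}, entering the free-ABA, free-protein
#'     and complex balances with matching signs. With production and
#'     degradation switched off this mode conserves `C_ABA + Complex` and
#'     `Protein + Complex`.}
#'   \item{`"literal"`}{The model equations exactly as printed:
#'     \eqn{dC_{ABA}/dt = k_{prod} - k_{deg} C_{ABA} - k_{on} Complex +
#'     k_{off} Complex}, \eqn{dComplex/dt = (k_{on}-k_{off}) Complex},
#'     and a protein balance with no binding term. Both binding rates act
#'     on the complex itself, so a complex starting at zero stays at zero
#'     (and the reporter then never lights up); this mode exists to
#'     reproduce the printed system's structure, not for physical realism.}
#' }
#'
#' @param state Named numeric vector or list with entries `C_ABA`, `mRNA`,
#'   `Protein`, `Complex`, `I_biolum`. All finite.
#' @param params A [biosensor_params()] object.
#' @param mode `"mass_action"` or `"literal"`.
#' @return Named numeric vector of derivatives in state order.
#' @examples
#' p <- biosensor_params()
#' s <- c(C_ABA = 1.5, mRNA = 0, Protein = 0, Complex = 0, I_biolum = 0)
#' biosensor_rhs(s, p)
#' @export
biosensor_rhs <- function(state, params, mode = "mass_action") {
  y <- .check_state(state, .BIOSENSOR_STATES)
  params <- .as_params(params, "biosensor_params", biosensor_params)
  .check_kinetics_mode(mode)
  d <- .rhs_biosensor(y, params, mode)
  names(d) <- .BIOSENSOR_STATES
  d
}

.SIGNALING_STATES <- c("C_ABA", "SNRK2", "PP2C", "MAPK")
.BIOSENSOR_STATES <- c("C_ABA", "mRNA", "Protein", "Complex", "I_biolum")

.check_state <- function(state, state_names) {
  y <- unlist(state, use.names = TRUE)
  if (!is.numeric(y)) stop("state must be numeric", call. = FALSE)
  if (!is.null(names(y)) && any(nzchar(names(y)))) {
    missing <- setdiff(state_names, names(y))
    if (length(missing)) {
      stop("state is missing entries: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    y <- y[state_names]
  } else if (length(y) != length(state_names)) {
    stop(sprintf("unnamed state must have %d entries (%s)",
                 length(state_names), paste(state_names, collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop("state entries must all be finite", call. = FALSE)
  }
  unname(y)
}

.as_params <- function(params, cls, ctor) {
  if (inherits(params, cls)) return(params)
  if (is.list(params)) return(do.call(ctor, params))
  stop(sprintf("params must be a %s object (see %s())", cls,
               deparse(substitute(ctor))), call. = FALSE)
}

# --- unchecked numeric cores (used by the integrators) ------------------

.rhs_signaling_aba <- function(y, p) {
  occ <- .hill_raw(max(y[1L], 0), p$K_half, p$n)
  c(p$k_synthesis - p$K1 * y[1L],
    p$K2 * occ,
    p$k_interact_SNRK2 * y[2L] - p$k_interact_PP2C * y[3L],
    -p$k_interact_SNRK2 * y[2L] + p$k_interact_MAPK * y[3L] +
      p$K3 * y[1L])
}

.rhs_signaling_noaba <- function(y, p) {
  c(0,
    -p$k_interact_MAPK * y[3L],
    p$k_interact_SNRK2 * y[2L] - p$k_interact_PP2C * y[3L],
    -p$k_interact_SNRK2 * y[2L] + p$k_interact_MAPK * y[3L])
}

.rhs_biosensor <- function(y, p, mode) {
  C <- y[1L]; m <- y[2L]; P <- y[3L]; X <- y[4L]
  occ_tr <- .hill_raw(max(C, 0), p$K_half, p$n)
  occ_rs <- .hill_raw(max(X, 0), p$K_half_response, p$n)
  dm <- p$k_trans * occ_tr - p$k_tran_deg * m
  dI <- p$k_response * occ_rs
  if (mode == "mass_action") {
    assoc <- p$kon * C * P
    dissoc <- p$koff * X
    c(p$k_prod - p$k_deg * C - assoc + dissoc,
      dm,
      p$k_tran_syn * m - p$k_deg_prot * P - assoc + dissoc,
      assoc - dissoc,
      dI)
  } else {
    c(p$k_prod - p$k_deg * C - p$kon * X + p$koff * X,
      dm,
      p$k_tran_syn * m - p$k_deg_prot * P,
      (p$kon - p$koff) * X,
      dI)
  }
}

# Flat parameter vectors handed to the compiled right-hand sides; order
# must match src/abasim_rhs.c.
.parms_signaling <- function(p) {
  c(p$k_synthesis, p$K1, p$K2, p$K3, p$k_interact_SNRK2,
    p$k_interact_PP2C, p$k_interact_MAPK, p$K_half, p$n)
}

.parms_biosensor <- function(p, mode) {
  c(p$k_prod, p$k_deg, p$kon, p$koff, p$k_trans, p$k_tran_deg,
    p$k_tran_syn, p$k_deg_prot, p$k_response, p$K_half,
    p$K_half_response, p$n, as.numeric(mode == "mass_action"))
}

# Model registry used by the integrators and the CLI.
.model_info <- function(model_id) {
  switch(model_id,
    signaling_aba = list(
      states = .SIGNALING_STATES,
      needs_mode = FALSE,
      param_class = "signaling_params",
      ctor = signaling_params,
      rhs = function(y, p, mode) .rhs_signaling_aba(y, p),
      c_func = "abasim_rhs_signaling_aba",
      c_init = "abasim_init_signaling",
      c_parms = function(p, mode) .parms_signaling(p),
      default_init = c(C_ABA = 1, SNRK2 = 1, PP2C = 1, MAPK = 1)),
    signaling_noaba = list(
      states = .SIGNALING_STATES,
      needs_mode = FALSE,
      param_class = "signaling_params",
      ctor = signaling_params,
      rhs = function(y, p, mode) .rhs_signaling_noaba(y, p),
      c_func = "abasim_rhs_signaling_noaba",
      c_init = "abasim_init_signaling",
      c_parms = function(p, mode) .parms_signaling(p),
      default_init = c(C_ABA = 0, SNRK2 = 1, PP2C = 1, MAPK = 1)),
    biosensor = list(
      states = .BIOSENSOR_STATES,
      needs_mode = TRUE,
      param_class = "biosensor_params",
      ctor = biosensor_params,
      rhs = function(y, p, mode) .rhs_biosensor(y, p, mode),
      c_func = "abasim_rhs_biosensor",
      c_init = "abasim_init_biosensor",
      c_parms = function(p, mode) .parms_biosensor(p, mode),
      default_init = c(C_ABA = 1.5, mRNA = 0, Protein = 0, Complex = 0,
                       I_biolum = 0)),
    stop(sprintf(
      "unknown model_id '%s' (expected signaling_aba, signaling_noaba or biosensor)",
      model_id), call. = FALSE)
  )
}

.default_params <- function(model_id) {
  info <- .model_info(model_id)
  info$ctor()
}
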