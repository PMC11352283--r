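#' Local parameter sensitivity of a simulated output
#'
#' Normalized local sensitivity coefficients
#' \deqn{S_p = \frac{p}{y}\,\frac{\partial y}{\partial p}
#'   \approx \frac{p}{y}\,\frac{y(p(1+h)) - y(p(1-h))}{2ph}}
#' computed by central finite differences with relative perturbation `h`,
#' one parameter at a time, all others held at their base values. The
#' coefficients are dimensionless elasticities: `S_p = +1` means a 1%
#' increase in `p` raises the output by 1%. A parameter the selected
#' model's right-hand side never reads (or whose base value is 0) gets a
#' coefficient of exactly 0.
#'
#' @param model_id Model to simulate (`"signaling_aba"`,
#'   `"signaling_noaba"`, `"biosensor"`).
#' @param params Base parameter set (`NULL` = model reference set).
#' @param output_spec What to measure: a list with `quantity` (`"final"`
#'   for the state at `t_end`, or `"steady"` for the [run_to_steady()]
#'   state) and `variable` (state-variable name). Default: final
#'   `I_biolum` for the biosensor, final last state variable otherwise.
#' @param perturbation Relative perturbation `h`, in `(0, 0.5]`
#'   (default 0.01).
#' @param settings A [solver_settings()] object.
#' @param mode Biosensor kinetics mode.
#' @param param_names Parameters to vary. Defaults to every parameter in
#'   the set; names not present in the set are reported with coefficient
#'   0 (useful when comparing across model families).
#' @param init_state Optional initial state (model default otherwise).
#'
#' @return A `sensitivity_matrix`: one-column numeric matrix of
#'   coefficients (rows = parameters), with attributes `perturbation`,
#'   `base_value` and `params_digest`.
#'
#' @examples
#' p <- biosensor_params(k_prod = 0.05, k_deg = 0.025)
#' s <- local_sensitivity("biosensor", p,
#'        output_spec = list(quantity = "steady", variable = "C_ABA"),
#'        settings = solver_settings(t_end = 2000),
#'        param_names = c("k_prod", "k_deg"))
#' s   # +1 and -1: the steady state k_prod/k_deg is homogeneous
#' @export
local_sensitivity <- function(model_id, params = NULL, output_spec = NULL,
                              perturbation = 0.01,
                              settings = solver_settings(),
                              mode = "mass_action", param_names = NULL,
                              init_state = NULL) {
  if (!is.numeric(perturbation) || length(perturbation) != 1L ||
      !is.finite(perturbation) || perturbation <= 0 || perturbation > 0.5) {
    stop("perturbation must lie in (0, 0.5]", call. = FALSE)
  }
  info <- .model_info(model_id)
  params <- if (is.null(params)) info$ctor() else
    .as_params(params, info$param_class, info$ctor)
  if (is.null(output_spec)) {
    output_spec <- list(quantity = "final",
                        variable = info$states[length(info$states)])
  }
  if (!output_spec$quantity %in% c("final", "steady")) {
    stop("output_spec$quantity must be \"final\" or \"steady\"",
         call. = FALSE)
  }
  if (!output_spec$variable %in% info$states) {
    stop(sprintf("output variable '%s' is not a state of model '%s'",
                 output_spec$variable, model_id), call. = FALSE)
  }
  if (is.null(param_names)) param_names <- names(params)

  eval_output <- function(p) {
    if (output_spec$quantity == "steady") {
      run_to_steady(model_id, p, init_state, settings,
                    mode)$state[[output_spec$variable]]
    } else {
      tr <- integrate_model(model_id, p, init_state, settings, mode)
      tr$states[nrow(tr$states), match(output_spec$variable, info$states)]
    }
  }
  y0 <- eval_output(params)
  if (y0 == 0) {
    stop("base output is 0; normalized sensitivities are undefined (consider absolute sensitivities)",
         call. = FALSE)
  }
  h <- perturbation
  coefs <- vapply(param_names, function(nm) {
    if (!nm %in% names(params)) return(0)
    p_base <- params[[nm]]
    if (p_base == 0) return(0)
    up <- params; up[[nm]] <- p_base * (1 + h)
    dn <- params; dn[[nm]] <- p_base * (1 - h)
    y_up <- eval_output(up)
    y_dn <- eval_output(dn)
    (p_base / y0) * (y_up - y_dn) / (2 * p_base * h)
  }, numeric(1))
  m <- matrix(coefs, ncol = 1,
              dimnames = list(param_names,
                              paste(output_spec$quantity,
                                    output_spec$variable, sep = "_")))
  structure(m, perturbation = h, base_value = y0,
            params_digest = params_digest(params),
            class = c("sensitivity_matrix", class(m)))
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf(
    "Normalized local sensitivities (central differences, h = %g; base output %.6g)\n",
    attr(x, "perturbation"), attr(x, "base_value")))
  m <- x
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(signif(m, 4))
  invisible(x)
}
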