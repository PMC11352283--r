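# On-disk formats: strict YAML run configuration, CSV tables with
# 17-significant-digit (round-trip-safe) numbers, and JSON provenance
# sidecars carrying everything needed to reproduce a run.

.CONFIG_KEYS <- list(
  top = c("model_id", "mode", "seed", "params", "init", "solver", "sweep",
          "fit", "output"),
  solver = c("rel_tol", "abs_tol", "t_end", "max_step", "steady_tol",
             "n_report"),
  sweep = c("levels", "from", "to", "count"),
  fit = c("free", "data", "n_starts"),
  output = c("path", "overwrite"))

#' Read and validate a run configuration
#'
#' Parses a YAML key-value configuration into a validated `run_config`
#' with all defaults applied. Unknown keys are rejected by name at every
#' level; parameter values are validated through the parameter
#' constructors, so e.g. a negative rate fails naming the offending key.
#'
#' The association rate must carry its unit in the key name: `kon_M`
#' (M^-1 s^-1, converted internally by 1e-6) or `kon_uM` (µM^-1 s^-1).
#' A bare `kon` key is rejected so that configurations are never
#' ambiguous about units.
#'
#' @param path Path to a YAML configuration file.
#'
#' @return A `run_config`: list with `model_id`, `mode`, `seed`,
#'   `params` (constructed parameter object), `init` (named state or
#'   NULL), `settings` ([solver_settings()]), `sweep` (levels vector or
#'   NULL), `fit` (list or NULL), `output` (list or NULL), and
#'   `effective` — the fully resolved configuration echoed into every
#'   output's metadata.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) {
                    stop(sprintf("config parse error in %s: %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  .reject_unknown(cfg, .CONFIG_KEYS$top, "top level")
  model_id <- cfg[["model_id"]] %||% "biosensor"
  info <- .model_info(model_id)
  mode <- cfg[["mode"]] %||% "mass_action"
  mode <- gsub("-", "_", mode)
  if (info$needs_mode) .check_kinetics_mode(mode)

  pblock <- cfg[["params"]] %||% list()
  if (model_id == "biosensor") {
    if ("kon" %in% names(pblock)) {
      stop("config key 'kon' must carry units: use 'kon_M' (M⁻¹s⁻¹) or 'kon_uM' (µM⁻¹s⁻¹)",
           call. = FALSE)
    }
    if ("kon_uM" %in% names(pblock)) {
      pblock$kon <- pblock$kon_uM
      pblock$kon_uM <- NULL
    }
    allowed <- c(setdiff(names(formals(biosensor_params)), "kon_M"),
                 "kon_M")
    .reject_unknown(pblock, allowed, "params")
  } else {
    .reject_unknown(pblock, names(formals(signaling_params)), "params")
  }
  params <- tryCatch(do.call(info$ctor, pblock),
                     error = function(e) {
                       stop(sprintf("config params invalid: %s",
                                    conditionMessage(e)), call. = FALSE)
                     })

  init <- cfg[["init"]]
  if (!is.null(init)) {
    .reject_unknown(init, info$states, "init")
    full <- info$default_init
    full[names(init)] <- unlist(init)
    init <- full
  }

  sblock <- cfg[["solver"]] %||% list()
  .reject_unknown(sblock, .CONFIG_KEYS$solver, "solver")
  settings <- do.call(solver_settings, sblock)

  sweep <- NULL
  if (!is.null(cfg[["sweep"]])) {
    .reject_unknown(cfg[["sweep"]], .CONFIG_KEYS$sweep, "sweep")
    sweep <- if (!is.null(cfg[["sweep"]][["levels"]])) {
      as.numeric(cfg[["sweep"]][["levels"]])
    } else {
      default_aba_levels(n = cfg[["sweep"]][["count"]] %||% 12,
                         from = cfg[["sweep"]][["from"]] %||% 1.5,
                         to = cfg[["sweep"]][["to"]] %||% 50)
    }
  }
  fit <- cfg[["fit"]]
  if (!is.null(fit)) .reject_unknown(fit, .CONFIG_KEYS$fit, "fit")
  output <- cfg[["output"]]
  if (!is.null(output)) {
    .reject_unknown(output, .CONFIG_KEYS$output, "output")
  }

  eff <- list(model_id = model_id,
              mode = if (info$needs_mode) mode else NULL,
              seed = cfg[["seed"]] %||% 1L,
              params = unclass(params),
              init = as.list(init %||% info$default_init),
              solver = unclass(settings),
              sweep = as.list(sweep), fit = fit, output = output)
  structure(list(model_id = model_id, mode = mode,
                 seed = cfg[["seed"]] %||% 1L, params = params, init = init,
                 settings = settings, sweep = sweep, fit = fit,
                 output = output, effective = eff),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.reject_unknown <- function(x, allowed, where) {
  if (is.null(names(x)) && length(x)) {
    stop(sprintf("config %s must be a mapping", where), call. = FALSE)
  }
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing_name <- names(x)[!nzchar(names(x))]
  if (length(missing_name)) {
    stop(sprintf("config %s contains an unnamed entry", where),
         call. = FALSE)
  }
  invisible(x)
}

# 17 significant digits: doubles survive a write/read round trip exactly.
.fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.write_csv17 <- function(df, path, overwrite) {
  if (file.exists(path) && !overwrite) {
    stop(sprintf("refusing to overwrite %s (set overwrite = TRUE)", path),
         call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("output directory does not exist: %s", dir),
         call. = FALSE)
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt17(out[[j]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                       ".json")

.write_metadata <- function(meta, path, overwrite) {
  if (file.exists(path) && !overwrite) {
    stop(sprintf("refusing to overwrite %s (set overwrite = TRUE)", path),
         call. = FALSE)
  }
  meta$package <- "abasim"
  meta$package_version <- as.character(utils::packageVersion("abasim"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a trajectory to CSV with a JSON provenance sidecar
#'
#' The CSV has header `time_s` followed by the state variables in the
#' model's documented order (`C_ABA,SNRK2,PP2C,MAPK` for the signaling
#' models; `C_ABA,mRNA,Protein,Complex,I_biolum` for the biosensor), with
#' numbers at 17 significant digits so a write/read round trip is
#' bit-exact. A sidecar `<path-without-ext>.json` records model id, mode,
#' parameters, and package version.
#'
#' @param trajectory An `aba_trajectory` from [integrate_model()] or
#'   [rk4_reference()].
#' @param path Output CSV path.
#' @param overwrite Overwrite existing files? Default `FALSE`.
#' @param extra_meta Optional named list merged into the sidecar (e.g.
#'   the effective run configuration).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, overwrite = FALSE,
                             extra_meta = NULL) {
  stopifnot(inherits(trajectory, "aba_trajectory"))
  df <- as.data.frame(trajectory)
  .write_csv17(df, path, overwrite)
  meta <- c(list(kind = "trajectory", model_id = trajectory$model_id,
                 mode = trajectory$mode,
                 params = unclass(trajectory$params),
                 params_digest = trajectory$params_digest,
                 n_report = length(trajectory$times),
                 t_end = max(trajectory$times)),
            extra_meta)
  .write_metadata(meta, .sidecar_path(path), overwrite)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path (the JSON sidecar is looked up next to it).
#' @return An `aba_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  info <- .model_info(meta$model_id)
  states <- as.matrix(df[, info$states, drop = FALSE])
  tr <- .new_trajectory(df$time_s, unname(states), meta$model_id,
                        if (is.null(meta$mode) || is.na(meta$mode))
                          "mass_action" else meta$mode,
                        do.call(info$ctor,
                                meta$params[names(meta$params) %in%
                                              names(formals(info$ctor))]),
                        info)
  tr
}

#' Write a dose-response table to CSV with a JSON sidecar
#'
#' Columns: `aba_initial_uM,I_final_RLU,converged`.
#'
#' @param table A `dose_response_table` from [dose_response()].
#' @inheritParams write_trajectory
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(table, path, overwrite = FALSE,
                                extra_meta = NULL) {
  stopifnot(inherits(table, "dose_response_table"))
  df <- data.frame(aba_initial_uM = table$aba_initial,
                   I_final_RLU = table$I_final,
                   converged = table$converged)
  .write_csv17(df, path, overwrite)
  meta <- c(list(kind = "dose_response", model_id = "biosensor",
                 mode = attr(table, "mode"),
                 params = unclass(attr(table, "params")),
                 params_digest = attr(table, "params_digest"),
                 t_end = attr(table, "t_end")),
            extra_meta)
  .write_metadata(meta, .sidecar_path(path), overwrite)
  invisible(path)
}

#' Write a synthetic plate to CSV with a JSON sidecar
#'
#' Columns: `aba_initial_uM,replicate,time_s,reading_RLU,flagged_negative`.
#' The sidecar records the generating (ground-truth) parameters, noise
#' model and seed.
#'
#' @param plate A `synthetic_plate`.
#' @inheritParams write_trajectory
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path, overwrite = FALSE,
                        extra_meta = NULL) {
  stopifnot(inherits(plate, "synthetic_plate"))
  df <- data.frame(aba_initial_uM = plate$aba_initial,
                   replicate = plate$replicate,
                   time_s = plate$time,
                   reading_RLU = plate$reading,
                   flagged_negative = plate$flagged_negative)
  .write_csv17(df, path, overwrite)
  meta <- c(list(kind = "synthetic_plate",
                 plate_kind = attr(plate, "kind"),
                 model_id = "biosensor", mode = attr(plate, "mode"),
                 params = unclass(attr(plate, "true_params")),
                 params_digest = attr(plate, "params_digest"),
                 noise_sd = attr(plate, "noise_sd"),
                 noise_type = attr(plate, "noise_type"),
                 seed = attr(plate, "seed")),
            extra_meta)
  .write_metadata(meta, .sidecar_path(path), overwrite)
  invisible(path)
}

#' Read a plate CSV written by [write_plate()]
#'
#' @param path CSV path.
#' @return A data frame usable by [fit_biosensor_params()] (columns
#'   `aba_initial`, `replicate`, `time`, `reading`, `flagged_negative`).
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path)
  data.frame(aba_initial = df$aba_initial_uM, replicate = df$replicate,
             time = df$time_s, reading = df$reading_RLU,
             flagged_negative = df$flagged_negative)
}

#' Write a fit or sensitivity result to JSON
#'
#' Serialises a [fit_hill()], [fit_biosensor_params()], [linearity_check()]
#' or [local_sensitivity()] result, with full-precision numbers, as a
#' self-describing JSON document.
#'
#' @param result A `hill_fit`, `biosensor_fit`, `linear_fit` or
#'   `sensitivity_matrix`.
#' @param path Output JSON path.
#' @inheritParams write_trajectory
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, overwrite = FALSE,
                         extra_meta = NULL) {
  meta <- if (inherits(result, "hill_fit")) {
    list(kind = "hill_fit", coefficients = as.list(result$coefficients),
         rss = result$rss, r2 = result$r2)
  } else if (inherits(result, "biosensor_fit")) {
    list(kind = "biosensor_fit", estimates = as.list(result$estimates),
         rss = result$rss, converged = result$converged,
         bound_active = as.list(result$bound_active),
         n_iterations = result$n_iterations, seed = result$seed,
         mode = result$mode, params_digest = result$params_digest)
  } else if (inherits(result, "linear_fit")) {
    list(kind = "linear_fit", slope = result$slope,
         intercept = result$intercept, r2 = result$r2)
  } else if (inherits(result, "sensitivity_matrix")) {
    list(kind = "sensitivity", output = colnames(result)[1L],
         perturbation = attr(result, "perturbation"),
         base_value = attr(result, "base_value"),
         coefficients = stats::setNames(as.list(as.numeric(result)),
                                        rownames(result)),
         params_digest = attr(result, "params_digest"))
  } else {
    stop("write_result(): unsupported result class", call. = FALSE)
  }
  .write_metadata(c(meta, extra_meta), path, overwrite)
  invisible(path)
}

#' Structurally validate a JSON metadata sidecar
#'
#' Checks a sidecar produced by the package's writers against the shipped
#' schema (`inst/schema/run-metadata-schema.json`): the required fields
#' must be present and of the right type.
#'
#' @param path Path to a sidecar JSON file.
#' @return `TRUE` invisibly, or an error naming the missing/invalid field.
#' @export
validate_metadata <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("kind", "package", "package_version")
  for (f in required) {
    if (is.null(meta[[f]]) || !is.character(meta[[f]])) {
      stop(sprintf("metadata field '%s' missing or not a string in %s",
                   f, path), call. = FALSE)
    }
  }
  if (!is.null(meta$params) && !is.list(meta$params)) {
    stop("metadata field 'params' must be a mapping", call. = FALSE)
  }
  invisible(TRUE)
}
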