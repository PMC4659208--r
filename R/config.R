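#' Default run configuration
#'
#' The defaults reproduce the reference parameterization end to end: resting
#' vitals 80/120 mmHg at 80 bpm, ICP 3 mmHg, total CBF 12.5 ml/s with a
#' 22/45/33 efferent split, outlet pressures 46/56/43.5 mmHg, the standard
#' whole-blood Carreau constants, the nominal geometry, right-ICA stenosis
#' over the 0/25/50/75/90/100 % grid, and all six variants.
#'
#' @return A nested named list (YAML-compatible).
#' @export
default_config <- function() {
  list(
    vitals = list(diastolic_pressure = 80, systolic_pressure = 120,
                  heart_rate = 80),
    perfusion = list(intracranial_pressure = 3, total_cbf = 12.5,
                     fraction_aca = 0.22, fraction_mca = 0.45,
                     fraction_pca = 0.33),
    outlet_pressures = list(ACA = 46, MCA = 56, PCA = 43.5),
    carreau = list(relaxation_time = 3.313, power_index = 0.3568,
                   mu_zero = 0.056, mu_inf = 0.00345),
    geometry = list(source = "nominal", seed = 1, jitter_fraction = 0,
                    path = NULL),
    stenosis = list(target_segment = "RICA", stenotic_length = 10),
    variants = COW_VARIANTS,
    degrees = c(0, 25, 50, 75, 90, 100),
    solver = list(max_iterations = 200, relative_tolerance = 1e-8,
                  under_relaxation = 0.5)
  )
}

check_unknown_keys <- function(supplied, reference, path = "") {
  if (!is.list(supplied)) return(invisible(NULL))
  if (is.null(names(supplied)) || all(names(supplied) == "")) {
    return(invisible(NULL))  # unnamed list = array value
  }
  unknown <- setdiff(names(supplied), names(reference))
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration key(s): ",
                 paste0(path, unknown, collapse = ", ")))
  }
  for (k in names(supplied)) {
    if (is.list(reference[[k]]) && !is.null(names(reference[[k]]))) {
      check_unknown_keys(supplied[[k]], reference[[k]], paste0(path, k, "."))
    }
  }
  invisible(NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (with their key paths),
#' fills in [default_config()] for everything unspecified, and validates the
#' result by constructing the corresponding parameter objects. An empty file
#' yields the full default run.
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#'
#' @return A validated configuration list of class \code{willisflow_config}.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("Config file not found: ", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  check_unknown_keys(user, defaults)
  config <- modifyList(defaults, user, keep.null = TRUE)
  validate_config(config)
}

validate_config <- function(config) {
  # constructing the objects runs all the invariant checks
  do.call(vital_signs, config$vitals)
  do.call(perfusion_constants, config$perfusion)
  do.call(carreau_parameters, config$carreau)
  do.call(solver_settings, config$solver)
  config$degrees <- as.numeric(unlist(config$degrees))
  config$variants <- as.character(unlist(config$variants))
  if (any(config$degrees < 0 | config$degrees > 100)) {
    abort("Configuration key degrees: values must lie in [0, 100].")
  }
  if (!all(config$variants %in% COW_VARIANTS)) {
    abort(paste0("Configuration key variants: must be among ",
                 paste(COW_VARIANTS, collapse = ", ")))
  }
  if (!config$geometry$source %in% c("nominal", "synthetic", "file")) {
    abort("Configuration key geometry.source: one of nominal, synthetic, file.")
  }
  if (config$geometry$source == "file" &&
      (is.null(config$geometry$path) || !file.exists(config$geometry$path))) {
    abort("Configuration key geometry.path: file must exist.")
  }
  structure(config, class = c("willisflow_config", "list"))
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the run objects described by a configuration
#'
#' Convenience constructors turning a configuration into the objects the
#' solver consumes.
#'
#' @param config A configuration from [load_config()] / [default_config()].
#'
#' @return \code{config_boundary()} a \code{boundary_set};
#'   \code{config_params()} a \code{carreau_parameters};
#'   \code{config_network()} a \code{cow_network} (uncalibrated);
#'   \code{config_settings()} a \code{solver_settings}.
#' @export
config_boundary <- function(config = default_config()) {
  build_boundary_set(
    vitals = do.call(vital_signs, config$vitals),
    constants = do.call(perfusion_constants, config$perfusion),
    outlet_pressures = unlist(config$outlet_pressures)
  )
}

#' @rdname config_boundary
#' @export
config_params <- function(config = default_config()) {
  do.call(carreau_parameters, config$carreau)
}

#' @rdname config_boundary
#' @export
config_settings <- function(config = default_config()) {
  do.call(solver_settings, config$solver)
}

#' @rdname config_boundary
#' @export
config_network <- function(config = default_config()) {
  dims <- switch(
    config$geometry$source,
    nominal = nominal_geometry(),
    synthetic = synthetic_geometry(config$geometry$seed,
                                   config$geometry$jitter_fraction),
    file = read_segments(config$geometry$path)
  )
  build_complete_cow(dims)
}
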