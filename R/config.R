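#' Default full configuration
#'
#' The complete nested configuration with every documented default: energy
#' constants (per-event ATP masses 4.1e4 and 1.2e8, set point 0.75, window
#' 5 s, kernel constants 20/100 ms, gate gain 300), stimulus rate 10 Hz, the
#' canonical LIF parameterization, STDP constants, and the 500E+125I network
#' composition.
#'
#' @return A named nested list with sections `neuron`, `energy`, `stdp`,
#'   `modulation`, `network`, `stimulus`, `simulation`.
#' @export
default_config <- function() {
  list(neuron = unclass(lif_params()),
       energy = unclass(energy_constants()),
       stdp = unclass(stdp_params()),
       modulation = unclass(modulation_params()),
       network = unclass(network_config()),
       stimulus = list(rate = 10, mode = "poisson"),
       simulation = unclass(simulation_config()))
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, overlays it on [default_config()], and
#' validates every section through the corresponding parameter constructor.
#' Unknown sections or keys, and out-of-range values, are all collected and
#' reported together.
#'
#' @param path Path to a YAML file (may be empty or contain any subset of
#'   sections/keys).
#' @return A validated configuration list whose sections carry the parameter
#'   classes (`lif_params`, `energy_constants`, ...).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
}

#' @rdname load_config
#' @param config A (possibly partial) configuration list instead of a file.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  problems <- character(0)
  bad_sections <- setdiff(names(config), names(defaults))
  if (length(bad_sections))
    problems <- c(problems, paste0("unknown section: ", bad_sections))
  merged <- defaults
  for (sec in intersect(names(config), names(defaults))) {
    bad_keys <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad_keys))
      problems <- c(problems,
                    paste0("unknown key: ", sec, "$", bad_keys))
    ok <- intersect(names(config[[sec]]), names(defaults[[sec]]))
    merged[[sec]] <- utils::modifyList(merged[[sec]], config[[sec]][ok])
  }
  ctors <- list(neuron = lif_params, energy = energy_constants,
                stdp = stdp_params, modulation = modulation_params,
                network = network_config, simulation = simulation_config)
  out <- merged
  for (sec in names(ctors)) {
    built <- tryCatch(do.call(ctors[[sec]], merged[[sec]]),
                      error = function(e) conditionMessage(e))
    if (is.character(built)) problems <- c(problems, built)
    else out[[sec]] <- built
  }
  if (!merged$stimulus$mode %in% c("poisson", "periodic"))
    problems <- c(problems, "stimulus$mode must be 'poisson' or 'periodic'")
  if (merged$stimulus$rate < 0)
    problems <- c(problems, "stimulus$rate must be >= 0")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  out
}

#' Save a configuration to YAML
#'
#' @param config A configuration list (classes are stripped; save/load
#'   round-trips to an identical validated configuration).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
save_config <- function(config, path) {
  plain <- lapply(config, function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.factor(v)) as.character(v) else v)
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Write a simulation summary as JSON
#'
#' @param result A `simulation_result` or experiment list with scalar summary
#'   fields.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_summary_json <- function(result, path) {
  s <- if (inherits(result, "simulation_result")) result$summary else result
  keep <- vapply(s, function(x) is.numeric(x) && length(x) == 1, logical(1))
  jsonlite::write_json(s[keep], path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
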