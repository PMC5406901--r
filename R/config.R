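# Flat key-value parameter configuration files (YAML or JSON).
#
# Each entry is either a bare number (a fixed parameter) or a mapping with
# `value:` and optionally `free: true`, marking the parameter as a target of
# inference.  Example:
#
#   model: ctmc
#   q1: {value: 0.01, free: true}
#   q2: {value: 0.01, free: true}
#   sigma_ext: {value: 0.3}

#' Read a model-parameter configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return list with `model` (`"branching"`, `"ctmc"` or `"discrete"`, may be
#'   `NULL`), `values` (named numeric vector of all parameters) and `free`
#'   (character vector of parameters flagged `free: true`).
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  model_id <- doc$model
  doc$model <- NULL
  values <- numeric(0)
  free <- character(0)
  for (nm in names(doc)) {
    entry <- doc[[nm]]
    if (is.list(entry)) {
      if (is.null(entry$value)) stop("parameter '", nm, "' has no value")
      values[nm] <- as.numeric(entry$value)
      if (isTRUE(entry$free)) free <- c(free, nm)
    } else {
      values[nm] <- as.numeric(entry)
    }
  }
  list(model = model_id, values = values, free = free)
}

#' Build a model from a configuration file
#'
#' @param path see [read_params_config()].
#' @return list with `model` (a `lineage_model`) and `free` (names of the
#'   parameters to infer).
#' @export
model_from_config <- function(path) {
  cfg <- read_params_config(path)
  ctor <- switch(cfg$model %||% "branching",
                 branching = branching_model,
                 ctmc = ctmc_model,
                 discrete = discrete_model,
                 stop("unknown model id: ", cfg$model))
  model <- do.call(ctor, as.list(cfg$values))
  list(model = model, free = cfg$free)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
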