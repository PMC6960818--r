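# File interfaces: readings/samples/predictions CSV, model JSON, config YAML.
# All CSV files are UTF-8, comma-separated, '.' decimal; readers validate
# required headers, report malformed rows with line numbers, and pass
# unknown extra columns through untouched.

check_columns <- function(d, required, path) {
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    rlang::abort(paste0(path, ": missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(d)
  if (nrow(pr)) {
    rlang::abort(paste0(
      path, ": malformed row(s) at line(s) ",
      paste(utils::head(unique(pr$row), 5), collapse = ", "),
      " (", nrow(pr), " problem(s) total)"
    ))
  }
  check_columns(d, required, path)
  d
}

#' Read and write session readings CSV
#'
#' One row per reading with columns `sample_id`, `step`, `rep`, `electrode`,
#' `target_ion`, `role`, `emf_mV` (EC rows carry mS/cm and
#' `electrode = "EC"`). Extra columns round-trip unchanged.
#'
#' @param readings Readings tibble ([simulate_session()]).
#' @param path File path.
#' @return `read_readings_csv()` returns the readings tibble.
#' @export
write_readings_csv <- function(readings, path) {
  check_columns(readings, c("sample_id", "step", "rep", "electrode",
                            "target_ion", "role", "emf_mV"), "readings")
  readr::write_csv(readings, path)
  invisible(path)
}

#' @rdname write_readings_csv
#' @export
read_readings_csv <- function(path) {
  read_checked_csv(path, c("sample_id", "step", "rep", "electrode",
                           "target_ion", "role", "emf_mV"))
}

#' Read and write solution-sample CSV
#'
#' One row per solution with `sample_id`, `role` and one mg/L column per
#' primary ion (background columns, if present, round-trip unchanged).
#'
#' @param samples Solution tibble.
#' @param path File path.
#' @export
write_samples_csv <- function(samples, path) {
  check_columns(samples, c("sample_id", "role", PRIMARY_IONS), "samples")
  readr::write_csv(samples, path)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  read_checked_csv(path, c("sample_id", "role", PRIMARY_IONS))
}

#' Read and write prediction CSV
#'
#' Columns: `sample_id`, `rep`, `method`, `ion`, `predicted_mgL`,
#' `measurable`.
#'
#' @param predictions Predictions tibble ([run_methods()]).
#' @param path File path.
#' @export
write_predictions_csv <- function(predictions, path) {
  check_columns(predictions, c("sample_id", "rep", "method", "ion",
                               "predicted_mgL", "measurable"), "predictions")
  readr::write_csv(predictions, path)
  invisible(path)
}

#' @rdname write_predictions_csv
#' @export
read_predictions_csv <- function(path) {
  read_checked_csv(path, c("sample_id", "rep", "method", "ion",
                           "predicted_mgL", "measurable"))
}

#' Serialise a fitted network to JSON and back
#'
#' The JSON file stores layer sizes, weights, biases, activation tags, both
#' min-max scalers and the training metadata (seed, epochs, final SSE), so
#' a fit can be reloaded and used for prediction without retraining.
#'
#' @param fit An `ann_fit`.
#' @param path File path.
#' @return `read_model_json()` returns the reconstructed `ann_fit`.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "ann_fit"))
  scaler_js <- function(s) list(features = s$features,
                                x_min = unname(s$x_min),
                                x_max = unname(s$x_max))
  obj <- list(
    layers = fit$net$layers,
    activations = fit$net$acts,
    weights = purrr::map(fit$net$w, ~ unclass(.x)),
    biases = fit$net$b,
    x_scaler = scaler_js(fit$x_scaler),
    y_scaler = scaler_js(fit$y_scaler),
    metadata = list(seed = fit$seed, epochs = fit$epochs,
                    converged = fit$converged, final_sse = fit$final_sse,
                    hidden = fit$hidden, activation = fit$activation)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler_r <- function(s) {
    structure(list(features = s$features,
                   x_min = stats::setNames(s$x_min, s$features),
                   x_max = stats::setNames(s$x_max, s$features)),
              class = "minmax_scaler")
  }
  w <- obj$weights
  if (is.matrix(w)) w <- list(w) # single-layer edge: simplifyVector collapses
  if (!is.list(w)) rlang::abort(paste0(path, ": malformed weights"))
  b <- obj$biases
  if (!is.list(b)) b <- list(b)
  net <- structure(list(layers = as.integer(obj$layers),
                        w = purrr::map(w, as.matrix),
                        b = purrr::map(b, as.numeric),
                        acts = obj$activations),
                   class = "ise_network")
  structure(list(
    net = net, x_scaler = scaler_r(obj$x_scaler),
    y_scaler = scaler_r(obj$y_scaler),
    trace = NULL, epochs = obj$metadata$epochs,
    converged = obj$metadata$converged, final_sse = obj$metadata$final_sse,
    hidden = obj$metadata$hidden, activation = obj$metadata$activation,
    seed = obj$metadata$seed
  ), class = "ann_fit")
}

#' Read and write experiment configuration YAML
#'
#' @param cfg Configuration list (see [default_config()]).
#' @param path File path.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  validate_config(yaml::read_yaml(path))
}
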