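# The end-to-end experiment runner: design -> simulate sessions -> train ->
# predict -> evaluate, deterministic from one master seed.

#' Default experiment configuration
#'
#' One list holding every knob of the simulated calibration campaign. The
#' defaults define the study conditions: the 27-run fractional design, 8
#' field samples measured in 3 replicate iterations, 0.5 mV electrode noise,
#' per-step offset drift of 0.15-0.45 mV with near-constant gain, the
#' literature-scale selectivity channels, and a 9-14-4 tansig network.
#'
#' @param seed Master seed; all per-stage streams are derived from it.
#' @return A named list of class-checked settings.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    levels = default_design_levels(),
    n_field = 8L,
    replicates = 3L,
    noise_sd = 0.5,
    ec_noise_sd = 0.02,
    drift = list(offset_range = c(0.15, 0.45), gain_max = 3e-4),
    ca_mg_logk = -0.7,
    mg_channels = TRUE,
    methods = c("tpn", "ann", "tpn-ann"),
    ann = list(hidden = 14L, max_epochs = 300L, lambda0 = 0.01, tol = 1e-9)
  )
}

#' Validate an experiment configuration
#'
#' @param cfg Configuration list.
#' @return The configuration, invisibly coerced where needed; aborts with a
#'   named field on the first invalid entry.
#' @export
validate_config <- function(cfg) {
  need <- names(default_config())
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    rlang::abort(paste0("config missing field(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != as.integer(cfg$seed)) {
    rlang::abort("config field `seed` must be a single integer")
  }
  if (!all(PRIMARY_IONS %in% names(cfg$levels))) {
    rlang::abort("config field `levels` must define NO3, K, Ca and Mg")
  }
  for (ion in PRIMARY_IONS) {
    lv <- cfg$levels[[ion]]
    if (length(lv) != 3 || is.unsorted(lv) || any(lv < 0)) {
      rlang::abort(paste0("config levels for ", ion,
                          " must be 3 ascending non-negative values"))
    }
  }
  if (cfg$n_field < 1) rlang::abort("config field `n_field` must be >= 1")
  if (cfg$replicates < 1) rlang::abort("config `replicates` must be >= 1")
  if (cfg$noise_sd < 0 || cfg$ec_noise_sd < 0) {
    rlang::abort("config noise SDs must be >= 0")
  }
  bad <- setdiff(cfg$methods, c("tpn", "ann", "tpn-ann"))
  if (length(bad)) {
    rlang::abort(paste0("unknown method(s) in config: ",
                        paste(bad, collapse = ", ")))
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full simulated calibration experiment
#'
#' Executes the software analogue of a measurement campaign: build the
#' 27-run fractional factorial training design and the normalization
#' standards; assign drift trajectories to the electrode array; simulate
#' the training session (drift on, as in a real campaign, so the raw-EMF
#' network is exposed to it); draw field samples and simulate their session
#' in replicate iterations with the drift continuing where training ended;
#' run the requested processing methods; and evaluate them against the
#' known field compositions. Fully deterministic given `cfg$seed`.
#'
#' @param cfg Configuration list (see [default_config()]).
#' @param out_dir Optional directory: artifacts (design, readings,
#'   predictions, models, report, config, log) are persisted stage by
#'   stage, so a failed run leaves its partial artifacts behind.
#' @param quiet Suppress per-stage messages?
#' @return An object of class `hybridcal_experiment`: config, electrode
#'   array, design/field truth tables, both sessions, models, predictions
#'   and the evaluation report.
#' @examples
#' \donttest{
#' ex <- run_experiment(default_config(seed = 7))
#' ex$report
#' }
#' @export
run_experiment <- function(cfg = default_config(), out_dir = NULL,
                           quiet = TRUE) {
  cfg <- validate_config(cfg)
  t0 <- Sys.time()
  log_lines <- character()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  persist <- function(fun, obj, file) {
    if (!is.null(out_dir)) fun(obj, file.path(out_dir, file))
  }
  stage <- function(name, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      rlang::abort(paste0("stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
    log_lines <<- c(log_lines, sprintf(
      "%s: ok (%.2fs)", name, as.numeric(Sys.time() - st, units = "secs")))
    if (!quiet) message(log_lines[length(log_lines)])
    out
  }
  seeds <- derive_seeds(cfg$seed, 5L)
  log_lines <- c(log_lines,
                 paste0("master seed: ", cfg$seed),
                 paste0("stage seeds: ", paste(seeds, collapse = " ")),
                 paste0("R version: ", R.version.string))

  design <- stage("design", {
    d <- generate_factorial_design(cfg$levels)
    persist(write_samples_csv, d, "design.csv")
    d
  })
  standards <- generate_normalization_pairs(cfg$levels)
  electrodes <- stage("electrodes", {
    el <- default_electrodes(
      noise_sd = cfg$noise_sd,
      ca_mg_logk = if (cfg$mg_channels) cfg$ca_mg_logk else -Inf
    )
    randomize_drift(el, seeds[1], cfg$drift$offset_range, cfg$drift$gain_max)
  })
  mg_on <- isTRUE(cfg$mg_channels)
  design_bg <- with_background(design, mg_sulfate = mg_on)
  standards_bg <- with_background(standards, mg_sulfate = mg_on)
  ec_excl <- if (mg_on) character() else "Mg"

  train_readings <- stage("simulate-training-session", {
    r <- simulate_session(design_bg, electrodes, standards_bg,
                          seed = seeds[2], start_step = 0L,
                          replicates = cfg$replicates,
                          ec_noise_sd = cfg$ec_noise_sd, ec_exclude = ec_excl)
    persist(write_readings_csv, r, "readings_train.csv")
    r
  })
  field <- stage("field-samples", {
    f <- generate_field_samples(cfg$n_field, cfg$levels, seeds[3])
    persist(write_samples_csv, f, "field_samples.csv")
    f
  })
  field_readings <- stage("simulate-field-session", {
    r <- simulate_session(with_background(field, mg_sulfate = mg_on),
                          electrodes, standards_bg, seed = seeds[4],
                          start_step = nrow(design),
                          replicates = cfg$replicates,
                          ec_noise_sd = cfg$ec_noise_sd, ec_exclude = ec_excl)
    persist(write_readings_csv, r, "readings_field.csv")
    r
  })
  if (length(cfg$methods) == 0L) {
    # simulation-only run: no methods requested, no predictions to evaluate
    log_lines <- c(log_lines, sprintf(
      "total: %.2fs", as.numeric(Sys.time() - t0, units = "secs")))
    if (!is.null(out_dir)) {
      write_config_yaml(cfg, file.path(out_dir, "config.yaml"))
      writeLines(log_lines, file.path(out_dir, "log.txt"))
    }
    return(structure(list(
      config = cfg, seeds = seeds, electrodes = electrodes,
      design = design, field = field,
      train_readings = train_readings, field_readings = field_readings,
      predictions = NULL, models = list(), report = NULL, log = log_lines
    ), class = "hybridcal_experiment"))
  }
  res <- stage("run-methods", {
    run_methods(train_readings, design, field_readings,
                methods = cfg$methods,
                curves = reference_curves(electrodes),
                levels = cfg$levels,
                hidden = cfg$ann$hidden, seed = seeds[5],
                max_epochs = cfg$ann$max_epochs,
                lambda0 = cfg$ann$lambda0, tol = cfg$ann$tol)
  })
  stage("persist-models", {
    if (!is.null(out_dir)) {
      persist(write_predictions_csv, res$predictions, "predictions.csv")
      for (m in names(res$models)) {
        write_model_json(res$models[[m]],
                         file.path(out_dir, paste0("model_", gsub("-", "_", m),
                                                   ".json")))
      }
    }
    NULL
  })
  report <- stage("evaluate", {
    rp <- compare_methods(res$predictions, field)
    if (!is.null(out_dir)) {
      readr::write_csv(rp, file.path(out_dir, "report.csv"))
      writeLines(render_report_markdown(rp, levels = cfg$levels),
                 file.path(out_dir, "report.md"))
    }
    rp
  })
  log_lines <- c(log_lines, sprintf(
    "total: %.2fs", as.numeric(Sys.time() - t0, units = "secs")))
  if (!is.null(out_dir)) {
    write_config_yaml(cfg, file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  structure(list(
    config = cfg, seeds = seeds, electrodes = electrodes,
    design = design, field = field,
    train_readings = train_readings, field_readings = field_readings,
    predictions = res$predictions, models = res$models, report = report,
    log = log_lines
  ), class = "hybridcal_experiment")
}

#' @export
print.hybridcal_experiment <- function(x, ...) {
  cat("<hybridcal_experiment> seed", x$config$seed, "-",
      nrow(x$design), "training +", nrow(x$field), "field samples,",
      "methods:", paste(x$config$methods, collapse = ", "), "\n")
  print(x$report)
  invisible(x)
}

#' Tidy the evaluation report of an experiment
#' @param x A `hybridcal_experiment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hybridcal_experiment <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' One-row summary of an experiment
#' @param x A `hybridcal_experiment`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.hybridcal_experiment <- function(x, ...) {
  tibble::tibble(
    seed = x$config$seed,
    n_training = nrow(x$design),
    n_field = nrow(x$field),
    replicates = x$config$replicates,
    methods = paste(x$config$methods, collapse = ","),
    mean_rmse_mgL = mean(x$report$rmse_mgL, na.rm = TRUE)
  )
}

#' Replicate the method comparison over independent seeded campaigns
#'
#' Repeats [run_experiment()] with per-replication seeds derived from
#' `seed` (fresh drift trajectories, noise, field samples and weight
#' initialisations each time) and collects the per-ion RMSE of every
#' method.
#'
#' @param n_reps Number of replications.
#' @param seed Master seed.
#' @param cfg Base configuration (its `seed` field is overwritten per
#'   replication).
#' @return Tibble: `replication`, `ion`, `method`, `rmse_mgL`.
#' @export
replicate_method_comparison <- function(n_reps = 20, seed = 1L,
                                        cfg = default_config()) {
  rep_seeds <- derive_seeds(seed, n_reps)
  purrr::map_dfr(seq_len(n_reps), function(i) {
    cfg$seed <- rep_seeds[i]
    ex <- run_experiment(cfg)
    dplyr::transmute(ex$report, replication = i, .data$ion, .data$method,
                     .data$rmse_mgL)
  })
}

#' Per-ion win fraction of the hybrid method across replications
#'
#' For every ion measurable by all methods, the fraction of replications in
#' which TPN-ANN attains the strictly lowest RMSE.
#'
#' @param comparison Tibble from [replicate_method_comparison()].
#' @param ions Ions to summarise (default NO3, K, Ca — those every method
#'   can predict).
#' @return Tibble: `ion`, `n_reps`, `hybrid_win_fraction`.
#' @export
summarize_ordering <- function(comparison, ions = c("NO3", "K", "Ca")) {
  comparison |>
    dplyr::filter(.data$ion %in% ions) |>
    dplyr::group_by(.data$ion, .data$replication) |>
    dplyr::summarise(
      win = .data$rmse_mgL[.data$method == "TPN-ANN"] == min(.data$rmse_mgL),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(n_reps = dplyr::n(),
                     hybrid_win_fraction = mean(.data$win),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$ion, PRIMARY_IONS))
}

#' Demonstrate the indirect-Mg inference mechanism
#'
#' Magnesium has no electrode of its own; the network infers it from the
#' traces Mg leaves in the other channels — the Mg response of the Ca
#' electrodes (Nikolsky cross-sensitivity) and the conductivity contributed
#' by Mg and its sulfate counter-ion. This study runs the hybrid campaign
#' twice: once with those channels enabled and once with both zeroed
#' (`mg_channels = FALSE`: Ca-Mg selectivity off, Mg and its sulfate removed
#' from the EC response). With the channels on, predicted Mg should track
#' the truth (R^2 well above zero); with them off, no Mg information reaches
#' the array and the R^2 collapses.
#'
#' @param seed Master seed.
#' @param n_field Number of field samples (more than the default campaign's
#'   8, so the R^2 contrast is estimated stably).
#' @param cfg Base configuration.
#' @return Tibble: `mg_channels`, `r_squared`, `rmse_mgL`, `n`.
#' @export
mg_inference_study <- function(seed = 1L, n_field = 24L,
                               cfg = default_config()) {
  cfg$n_field <- as.integer(n_field)
  cfg$methods <- "tpn-ann"
  purrr::map_dfr(c(TRUE, FALSE), function(on) {
    cfg$mg_channels <- on
    cfg$seed <- as.integer(seed)
    ex <- run_experiment(cfg)
    row <- ex$report[ex$report$ion == "Mg" & ex$report$method == "TPN-ANN", ]
    tibble::tibble(
      mg_channels = on,
      r_squared = ifelse(is.na(row$r_squared), 0, row$r_squared),
      rmse_mgL = row$rmse_mgL,
      n = row$n
    )
  })
}
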