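# The hybrid pipeline: assemble signal tables (raw or TPN-corrected) and run
# the three processing methods over a measurement campaign.

#' Fixed input-signal column order for the network
#' @format Character vector: eight electrode ids then `"EC"`.
#' @export
SIGNAL_COLUMNS <- c("NO3_1", "NO3_2", "NO3_3", "K_1", "K_2", "K_3",
                    "Ca_1", "Ca_2", "EC")

#' Build the network's signal/composition tables from a session
#'
#' Pivots session readings into the fixed 9-column signal layout (eight ISE
#' EMFs in mV plus EC in mS/cm) and aligns the known compositions. For the
#' hybrid method the ISE columns are TPN-corrected first; EC is never
#' TPN-corrected. With an undrifted, identity normalization context the two
#' layouts coincide.
#'
#' @param readings Session tibble from [simulate_session()].
#' @param truth Solution tibble with `sample_id` and mg/L columns for the
#'   four primary ions (omit for prediction-only tables).
#' @param method `"ann"` (raw EMFs) or `"tpn-ann"` (corrected EMFs).
#' @param curves Reference curves (required for `"tpn-ann"`).
#' @param levels Design levels (normalization standards).
#' @return List: `x` (tibble, columns [SIGNAL_COLUMNS]), `y` (tibble of mg/L
#'   targets or `NULL`), `meta` (tibble `sample_id`, `rep`).
#' @export
build_training_table <- function(readings, truth = NULL,
                                 method = c("ann", "tpn-ann"),
                                 curves = NULL,
                                 levels = default_design_levels()) {
  method <- match.arg(method)
  samp <- readings[readings$role == "sample", ]
  if (method == "tpn-ann") {
    if (is.null(curves)) rlang::abort("`curves` needed for the hybrid method")
    if (!any(readings$role != "sample")) {
      rlang::abort("no normalization readings in session: cannot TPN-correct")
    }
    samp <- tpn_correct_readings(readings, curves, levels)
  }
  wide <- samp |>
    dplyr::select("sample_id", "rep", "electrode", "emf_mV") |>
    tidyr::pivot_wider(names_from = "electrode", values_from = "emf_mV")
  miss <- setdiff(SIGNAL_COLUMNS, names(wide))
  if (length(miss)) {
    rlang::abort(paste0("session lacks signal column(s): ",
                        paste(miss, collapse = ", ")))
  }
  meta <- dplyr::select(wide, "sample_id", "rep")
  x <- dplyr::select(wide, dplyr::all_of(SIGNAL_COLUMNS))
  y <- NULL
  if (!is.null(truth)) {
    y <- meta |>
      dplyr::left_join(
        dplyr::select(truth, "sample_id", dplyr::all_of(PRIMARY_IONS)),
        by = "sample_id"
      ) |>
      dplyr::select(dplyr::all_of(PRIMARY_IONS))
    if (anyNA(y)) rlang::abort("truth table is missing some sample_ids")
  }
  list(x = x, y = y, meta = meta)
}

#' Run the TPN, ANN and hybrid TPN-ANN methods over a campaign
#'
#' Trains (where applicable) on the training session and predicts every
#' replicate measurement of the test session:
#' * `"tpn"` — per-measurement two-point normalization and Nernst inversion;
#'   predicts only ions with a dedicated electrode (no Mg).
#' * `"ann"` — network trained on raw EMFs; predicts all four ions.
#' * `"tpn-ann"` — network trained and evaluated on TPN-corrected EMFs.
#'
#' @param train_readings,train_truth Training session readings and known
#'   compositions.
#' @param test_readings Test session readings (may contain replicate
#'   iterations per sample).
#' @param methods Subset of `c("tpn", "ann", "tpn-ann")`.
#' @param curves Reference calibration curves.
#' @param levels Design levels.
#' @param hidden,seed,max_epochs,lambda0,tol Network settings (see
#'   [ann_train()]); each network method derives its own init seed.
#' @return List: `predictions` (tibble `sample_id`, `rep`, `method`, `ion`,
#'   `predicted_mgL`, `measurable`) and `models` (named list of `ann_fit`
#'   objects for the network methods).
#' @export
run_methods <- function(train_readings, train_truth, test_readings,
                        methods = c("tpn", "ann", "tpn-ann"),
                        curves = reference_curves(default_electrodes()),
                        levels = default_design_levels(),
                        hidden = 14, seed = 1L, max_epochs = 300,
                        lambda0 = 0.01, tol = 1e-9) {
  methods <- match.arg(methods, c("tpn", "ann", "tpn-ann"),
                       several.ok = TRUE)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2))
  preds <- list(); models <- list()

  if ("tpn" %in% methods) {
    tp <- tpn_predict(test_readings, curves, levels)
    preds$tpn <- tp |>
      dplyr::transmute(.data$sample_id, .data$rep, method = "TPN",
                       .data$ion, .data$predicted_mgL, .data$measurable)
  }
  for (m in intersect(c("ann", "tpn-ann"), methods)) {
    tab <- build_training_table(train_readings, train_truth, method = m,
                                curves = curves, levels = levels)
    # early-stopping split: with replicate iterations, hold out the last
    # iteration (same solutions, fresh noise) so design coverage is intact;
    # otherwise fall back to holding out whole solutions
    val_rows <- NULL
    if (max(tab$meta$rep) > 1) {
      val_rows <- which(tab$meta$rep == max(tab$meta$rep))
    }
    fit <- ann_train(tab$x, tab$y, hidden = hidden,
                     seed = seeds[if (m == "ann") 1 else 2],
                     max_epochs = max_epochs, lambda0 = lambda0, tol = tol,
                     groups = tab$meta$sample_id, val_rows = val_rows,
                     patience = 40L, restarts = 3L)
    models[[m]] <- fit
    test_tab <- build_training_table(test_readings, NULL, method = m,
                                     curves = curves, levels = levels)
    out <- predict(fit, test_tab$x)
    preds[[m]] <- dplyr::bind_cols(test_tab$meta, out) |>
      tidyr::pivot_longer(dplyr::all_of(PRIMARY_IONS), names_to = "ion",
                          values_to = "predicted_mgL") |>
      dplyr::mutate(method = toupper(m), measurable = TRUE,
                    .after = "rep")
  }
  list(predictions = dplyr::bind_rows(preds), models = models)
}
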