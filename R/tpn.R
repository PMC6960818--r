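# Two-point normalization (TPN): per-measurement drift correction of raw
# EMFs against low/high standards, followed by Nernst inversion.

#' Two-point normalization of a raw EMF
#'
#' Sensitivity step: the EMF is multiplied by the ratio of the reference EMF
#' difference to the measured EMF difference between the two standards,
#' `r = (E_ref_high - E_ref_low) / (E_meas_high - E_meas_low)`. Offset step:
#' the difference between the rescaled high-standard reading and the
#' reference high point is subtracted, so the high standard maps exactly
#' onto the reference curve:
#'
#' corrected = emf * r - (E_meas_high * r - E_ref_high)
#'
#' For a purely Nernstian electrode under any gain `g > 0` and offset drift
#' `d`, this restores the undrifted EMF exactly; when the measured pair
#' equals the reference pair the correction is the identity.
#'
#' @param emf Raw EMF(s) in mV.
#' @param ref_low,ref_high Reference EMFs of the low/high standards (mV),
#'   from the electrode's calibration curve.
#' @param meas_low,meas_high Measured EMFs of the standards in this session
#'   (mV).
#' @return Corrected EMF(s) in mV.
#' @export
tpn_correct <- function(emf, ref_low, ref_high, meas_low, meas_high) {
  d_ref <- ref_high - ref_low
  d_meas <- meas_high - meas_low
  if (!is.finite(d_meas) || abs(d_meas) < 1e-9) {
    rlang::abort("measured standard EMFs are equal: dead electrode")
  }
  if (!is.finite(d_ref) || abs(d_ref) < 1e-9) {
    rlang::abort("reference standard EMFs are equal: invalid context")
  }
  r <- d_ref / d_meas
  emf * r - (meas_high * r - ref_high)
}

#' Reference EMFs of the normalization standards for each electrode
#'
#' @param curves Reference curves tibble (see [reference_curves()]).
#' @param levels Design levels; extremes define the standards.
#' @return `curves` with `ref_low` and `ref_high` columns (mV).
#' @keywords internal
standard_reference_emfs <- function(curves, levels = default_design_levels()) {
  curves$ref_low <- NA_real_
  curves$ref_high <- NA_real_
  for (i in seq_len(nrow(curves))) {
    ion <- curves$ion[i]
    lv <- levels[[ion]]
    if (is.null(lv)) rlang::abort(paste0("no design levels for ion ", ion))
    curves$ref_low[i] <- ideal_emf(mgL_to_molar(lv[1], ion),
                                   curves$slope[i], curves$e0j[i])
    curves$ref_high[i] <- ideal_emf(mgL_to_molar(lv[3], ion),
                                    curves$slope[i], curves$e0j[i])
  }
  curves
}

#' Apply TPN to all sample readings of a session
#'
#' Each ISE reading of role `"sample"` is corrected with the normalization
#' pair measured by the same electrode immediately before the same sample.
#' EC readings are passed through unchanged (conductivity is not an EMF and
#' is never normalized).
#'
#' @param readings Session tibble from [simulate_session()] (or read back
#'   from CSV).
#' @param curves Reference curves tibble.
#' @param levels Design levels defining the standards.
#' @return `readings` restricted to role `"sample"`, with `emf_mV` replaced
#'   by the corrected value for ISE rows.
#' @export
tpn_correct_readings <- function(readings, curves,
                                 levels = default_design_levels()) {
  curves <- standard_reference_emfs(curves, levels)
  norm <- readings[readings$role != "sample", ]
  out <- readings[readings$role == "sample", ]
  for (i in seq_len(nrow(out))) {
    if (out$electrode[i] == "EC") next
    cv <- curves[curves$electrode == out$electrode[i], ]
    if (nrow(cv) != 1L) {
      rlang::abort(paste0("no reference curve for electrode ", out$electrode[i]))
    }
    pair <- norm[norm$sample_id == out$sample_id[i] &
                   norm$electrode == out$electrode[i], ]
    ml <- pair$emf_mV[pair$role == "norm_low"]
    mh <- pair$emf_mV[pair$role == "norm_high"]
    if (length(ml) != 1L || length(mh) != 1L) {
      rlang::abort(paste0("missing normalization pair for sample ",
                          out$sample_id[i], ", electrode ", out$electrode[i]))
    }
    out$emf_mV[i] <- tpn_correct(out$emf_mV[i], cv$ref_low, cv$ref_high, ml, mh)
  }
  out
}

#' Predict ion concentrations by the TPN method
#'
#' For every sample reading: TPN-correct the EMF, invert the simplified
#' Nernst model with the electrode's reference curve, convert to mg/L, and
#' average replicate electrodes of the same ion (unweighted mean of
#' concentration predictions). Ions without a dedicated electrode (Mg in the
#' default array) are reported as not measurable — the TPN method has no
#' predictability for ions lacking a directly related sensor.
#'
#' Predictions are reported unclamped; values outside the calibrated design
#' range are flagged in the `flag` column, never truncated.
#'
#' @param readings Session tibble from [simulate_session()].
#' @param curves Reference curves tibble.
#' @param levels Design levels (standards + range flags).
#' @param ions Ions to report (default the four primary nutrients).
#' @param exclude_electrodes Electrode ids to drop (e.g. flagged dead); a
#'   warning reports the reduced averaging basis.
#' @return Tibble with `sample_id`, `rep`, `ion`, `predicted_mgL`,
#'   `n_electrodes`, `sd_mgL`, `measurable`, `flag`.
#' @export
tpn_predict <- function(readings, curves, levels = default_design_levels(),
                        ions = PRIMARY_IONS, exclude_electrodes = character()) {
  if (length(exclude_electrodes)) {
    rlang::warn(paste0("excluding electrode(s) ",
                       paste(exclude_electrodes, collapse = ", "),
                       "; replicate means use the remaining electrodes"))
    readings <- readings[!readings$electrode %in% exclude_electrodes, ]
  }
  corrected <- tpn_correct_readings(readings, curves, levels)
  corrected <- corrected[corrected$electrode != "EC", ]
  corrected <- dplyr::left_join(
    corrected, dplyr::select(curves, "electrode", "slope", "e0j"),
    by = "electrode"
  )
  corrected$pred <- NA_real_
  for (i in seq_len(nrow(corrected))) {
    corrected$pred[i] <- invert_nernst(
      corrected$emf_mV[i], corrected$slope[i], corrected$e0j[i],
      corrected$target_ion[i]
    )
  }
  per_ion <- corrected |>
    dplyr::group_by(.data$sample_id, .data$rep, ion = .data$target_ion) |>
    dplyr::summarise(
      predicted_mgL = mean(.data$pred),
      n_electrodes = dplyr::n(),
      sd_mgL = stats::sd(.data$pred),
      .groups = "drop"
    ) |>
    dplyr::mutate(measurable = TRUE)

  missing_ions <- setdiff(ions, unique(per_ion$ion))
  if (length(missing_ions)) {
    pad <- tidyr::expand_grid(
      dplyr::distinct(per_ion, .data$sample_id, .data$rep),
      ion = missing_ions
    ) |>
      dplyr::mutate(predicted_mgL = NA_real_, n_electrodes = 0L,
                    sd_mgL = NA_real_, measurable = FALSE)
    per_ion <- dplyr::bind_rows(per_ion, pad)
  }
  per_ion <- per_ion[per_ion$ion %in% ions, ]
  per_ion$flag <- "ok"
  for (i in seq_len(nrow(per_ion))) {
    lv <- levels[[per_ion$ion[i]]]
    p <- per_ion$predicted_mgL[i]
    if (!is.na(p) && !is.null(lv) && (p < 0 || p < lv[1] / 2 || p > lv[3] * 2)) {
      per_ion$flag[i] <- "out_of_range"
    }
  }
  dplyr::arrange(per_ion, .data$sample_id, .data$rep,
                 match(.data$ion, PRIMARY_IONS))
}
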