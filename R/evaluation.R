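# Accuracy and precision metrics: RMSE, replicate CV, OLS slope with 95% CI.

#' Root mean square error
#'
#' `sqrt(mean((predicted - actual)^2))` — population-N denominator.
#'
#' @param predicted,actual Equal-length non-empty numeric vectors.
#' @return RMSE in the units of the inputs.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual)) {
    rlang::abort("`predicted` and `actual` must be non-empty and equal length")
  }
  sqrt(mean((predicted - actual)^2))
}

#' Coefficient of variation across replicate measurements
#'
#' Per-sample SDs use the (N-1) denominator around the per-sample replicate
#' mean. The primary (pooled) CV is `sqrt(mean per-sample variance) /
#' grand mean * 100`; the per-sample-averaged CV (`mean of SD_i / mean_i *
#' 100`) is reported alongside, since either aggregation is defensible.
#'
#' @param values Replicate predictions.
#' @param sample Sample identifier aligned with `values` (a single sample is
#'   assumed if omitted).
#' @return One-row tibble: `cv` (pooled, %), `cv_avg` (mean per-sample CV,
#'   %), `n_samples`.
#' @examples
#' cv_percent(c(9, 10, 11)) # CV 10%
#' @export
cv_percent <- function(values, sample = NULL) {
  if (is.null(sample)) sample <- rep(1L, length(values))
  stopifnot(length(values) == length(sample))
  d <- tibble::tibble(v = values, s = sample) |>
    dplyr::group_by(.data$s) |>
    dplyr::summarise(m = mean(.data$v), sd = stats::sd(.data$v),
                     n = dplyr::n(), .groups = "drop")
  if (any(d$n < 2)) {
    rlang::abort("every sample needs >= 2 replicates for a CV")
  }
  tibble::tibble(
    cv = sqrt(mean(d$sd^2)) / mean(values) * 100,
    cv_avg = mean(d$sd / d$m * 100),
    n_samples = nrow(d)
  )
}

#' Ordinary least-squares fit with a t-based 95% slope CI
#'
#' Regresses the reference concentrations (Y) on the predicted
#' concentrations (X) — the convention under which method biases appear as
#' slopes away from 1 — and reports slope, intercept, R^2 and the two-sided
#' 95% confidence interval of the slope.
#'
#' @param predicted Predicted concentrations (regressor X).
#' @param actual Reference concentrations (response Y).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `conf_low`,
#'   `conf_high`, `n`.
#' @examples
#' ols_with_ci(c(0, 1, 2), c(0, 2, 4)) # slope 2, R^2 1
#' @export
ols_with_ci <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  if (length(predicted) < 3) rlang::abort("need >= 3 points for the CI")
  if (stats::sd(predicted) == 0) rlang::abort("constant predictions: no slope")
  fit <- stats::lm(actual ~ predicted)
  # suppressWarnings: summary.lm (also inside confint/vcov) warns when the
  # fit is exactly perfect, which legitimately happens on synthetic data
  ci <- suppressWarnings(stats::confint(fit, "predicted", level = 0.95))
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    # suppressWarnings: summary.lm warns on an exactly perfect fit
    r_squared = suppressWarnings(summary(fit)$r.squared),
    conf_low = ci[1], conf_high = ci[2],
    n = length(predicted)
  )
}

#' Compare processing methods on a common set of samples
#'
#' Aggregates a predictions table (replicates included) against the known
#' compositions into one row per measurable (ion, method) pair: RMSE of the
#' per-sample replicate means, pooled replicate CV, and the OLS statistics
#' of reference vs prediction. Combinations reported as not measurable
#' (the TPN method for Mg) carry no metric row; [render_report_markdown()]
#' prints them as "Not measurable".
#'
#' @param predictions Tibble from [run_methods()] (`sample_id`, `rep`,
#'   `method`, `ion`, `predicted_mgL`, `measurable`).
#' @param truth Solution tibble with `sample_id` and mg/L columns.
#' @return An `eval_report` tibble: `ion`, `method`, `n`, `rmse_mgL`,
#'   `cv_pct`, `cv_avg_pct`, `r_squared`, `slope`, `intercept`,
#'   `conf_low`, `conf_high`.
#' @export
compare_methods <- function(predictions, truth) {
  meas <- predictions[predictions$measurable, ]
  truth_long <- truth |>
    dplyr::select("sample_id", dplyr::all_of(intersect(PRIMARY_IONS,
                                                       names(truth)))) |>
    tidyr::pivot_longer(-"sample_id", names_to = "ion",
                        values_to = "actual_mgL")
  joined <- dplyr::inner_join(meas, truth_long, by = c("sample_id", "ion"))
  if (nrow(joined) == 0L) rlang::abort("predictions and truth do not align")

  out <- joined |>
    dplyr::group_by(.data$ion, .data$method) |>
    dplyr::group_modify(function(d, key) {
      per_sample <- d |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(pred = mean(.data$predicted_mgL),
                         actual = .data$actual_mgL[1],
                         n_rep = dplyr::n(), .groups = "drop")
      row <- tibble::tibble(
        n = nrow(per_sample),
        rmse_mgL = rmse(per_sample$pred, per_sample$actual),
        cv_pct = NA_real_, cv_avg_pct = NA_real_,
        r_squared = NA_real_, slope = NA_real_, intercept = NA_real_,
        conf_low = NA_real_, conf_high = NA_real_
      )
      if (all(per_sample$n_rep >= 2)) {
        cv <- cv_percent(d$predicted_mgL, d$sample_id)
        row$cv_pct <- cv$cv; row$cv_avg_pct <- cv$cv_avg
      }
      ols <- tryCatch(ols_with_ci(per_sample$pred, per_sample$actual),
                      error = function(e) NULL)
      if (!is.null(ols)) {
        row$r_squared <- ols$r_squared; row$slope <- ols$slope
        row$intercept <- ols$intercept
        row$conf_low <- ols$conf_low; row$conf_high <- ols$conf_high
      }
      row
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$ion, PRIMARY_IONS), .data$method)
  class(out) <- c("eval_report", class(out))
  out
}

#' Render an evaluation report as a markdown table
#'
#' One display row per (ion, method), including "Not measurable" lines for
#' method/ion combinations without predictions (the TPN method for Mg).
#'
#' @param report An `eval_report` from [compare_methods()].
#' @param methods Methods to display (default: those present plus TPN).
#' @param levels Design levels, used to print each ion's range.
#' @return A character scalar of markdown.
#' @export
render_report_markdown <- function(report,
                                   methods = unique(report$method),
                                   levels = default_design_levels()) {
  lines <- c(
    "| Ion | Range (mg/L) | Method | RMSE (mg/L) | CV (%) | R^2 |",
    "|---|---|---|---|---|---|"
  )
  for (ion in PRIMARY_IONS) {
    rng <- if (!is.null(levels[[ion]])) {
      paste0(min(levels[[ion]]), "-", max(levels[[ion]]))
    } else ""
    for (m in methods) {
      row <- report[report$ion == ion & report$method == m, ]
      if (nrow(row) == 0L) {
        lines <- c(lines, sprintf("| %s | %s | %s | Not measurable | | |",
                                  ion, rng, m))
      } else {
        lines <- c(lines, sprintf(
          "| %s | %s | %s | %.1f | %s | %s |", ion, rng, m, row$rmse_mgL,
          ifelse(is.na(row$cv_pct), "", sprintf("%.1f", row$cv_pct)),
          ifelse(is.na(row$r_squared), "", sprintf("%.2f", row$r_squared))
        ))
      }
    }
  }
  paste(lines, collapse = "\n")
}
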