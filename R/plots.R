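# ggplot2 views of the main result objects.

#' Plot predicted vs actual concentrations of an experiment
#'
#' One panel per ion, colour per processing method, with the 1:1 line;
#' replicate iterations are averaged per sample.
#'
#' @param object A `hybridcal_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hybridcal_experiment <- function(object, ...) {
  truth_long <- object$field |>
    dplyr::select("sample_id", dplyr::all_of(PRIMARY_IONS)) |>
    tidyr::pivot_longer(-"sample_id", names_to = "ion",
                        values_to = "actual_mgL")
  d <- object$predictions |>
    dplyr::filter(.data$measurable) |>
    dplyr::group_by(.data$sample_id, .data$method, .data$ion) |>
    dplyr::summarise(predicted_mgL = mean(.data$predicted_mgL),
                     .groups = "drop") |>
    dplyr::inner_join(truth_long, by = c("sample_id", "ion")) |>
    dplyr::mutate(ion = factor(.data$ion, PRIMARY_IONS))
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted_mgL, .data$actual_mgL,
                                  colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::facet_wrap(~ion, scales = "free") +
    ggplot2::labs(x = "Predicted concentration (mg/L)",
                  y = "Actual concentration (mg/L)",
                  colour = "Method") +
    ggplot2::theme_bw()
}

#' Plot a structure-search report
#'
#' Mean training RMSE (scaled units) with SD error bars over the replicate
#' trainings, one panel for the hidden-layer scan and one for the
#' hidden-neuron scan.
#'
#' @param object A `structure_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.structure_search <- function(object, ...) {
  d <- tidy.structure_search(object) |>
    dplyr::mutate(phase = factor(.data$phase, c("layers", "neurons"),
                                 c("Hidden layers", "Hidden neurons")))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$candidate), .data$mean_rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rmse - .data$sd_rmse,
                                        ymax = .data$mean_rmse + .data$sd_rmse),
                           width = 0.25) +
    ggplot2::facet_wrap(~phase, scales = "free_x") +
    ggplot2::labs(x = "Candidate", y = "Training RMSE (scaled)") +
    ggplot2::theme_bw()
}

#' Plot the training loss trace of a fitted network
#'
#' Accepted-step sum of squared errors per Levenberg-Marquardt epoch (log
#' scale); non-increasing by construction.
#'
#' @param object An `ann_fit` (must retain its trace, i.e. not reloaded
#'   from JSON).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ann_fit <- function(object, ...) {
  if (is.null(object$trace)) {
    rlang::abort("this fit has no stored loss trace")
  }
  d <- tibble::tibble(epoch = seq_along(object$trace) - 1L,
                      sse = object$trace)
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$sse)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Accepted LM epoch", y = "Training SSE (scaled)") +
    ggplot2::theme_bw()
}
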