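# Two-phase trial-and-error search over the network structure.

#' Search the network structure: hidden layers, then hidden neurons
#'
#' Phase 1 fixes the per-layer hidden-neuron count (default 10) and trains
#' candidate depths of 1, 2, 3, 5 and 10 hidden layers; tansig is used for
#' depths up to 3 and ReLU for the deeper nets (where tanh's bounded output
#' attenuates the signal layer by layer). Phase 2 fixes the winning depth
#' and scans 8-16 hidden neurons in steps of 2. Every cell is trained in
#' replicate (default 3) from distinct seeded initialisations, and the cell
#' score is the mean over replicates of the training RMSE on the scaled
#' outputs (so the four ions weigh comparably). The selected structure is
#' the argmin of the mean RMSE; ties go to the smaller structure (fewer
#' parameters). Cells whose every replicate fails to train are excluded
#' with a warning.
#'
#' @param x,y Raw input-signal and composition tables (see [ann_train()]).
#' @param layer_counts Candidate hidden-layer counts for phase 1.
#' @param neuron_counts Candidate per-layer neuron counts for phase 2.
#' @param reps Replicate trainings per cell.
#' @param phase1_neurons Hidden neurons per layer during phase 1.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param max_epochs,lambda0,tol Passed to the trainer.
#' @return An object of class `structure_search`: tibbles `phase1` and
#'   `phase2` (candidate, mean/sd RMSE over replicates, n, activation) and
#'   `best` (`layers`, `neurons`, `activation`).
#' @export
structure_search <- function(x, y,
                             layer_counts = c(1, 2, 3, 5, 10),
                             neuron_counts = seq(8, 16, by = 2),
                             reps = 3, phase1_neurons = 10, seed = 1L,
                             max_epochs = 150, lambda0 = 0.01, tol = 1e-9) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  n_cells <- length(layer_counts) + length(neuron_counts)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L,
                                       n_cells * reps))
  seed_mat <- matrix(seeds, nrow = reps)
  ys <- fit_scaler(y)
  y_scaled <- apply_scaler(ys, y)

  cell_rmse <- function(hidden, activation, cell_idx) {
    vapply(seq_len(reps), function(r) {
      fit <- tryCatch(
        ann_train(x, y, hidden = hidden, activation = activation,
                  seed = seed_mat[r, cell_idx], max_epochs = max_epochs,
                  lambda0 = lambda0, tol = tol),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NA_real_)
      pred_scaled <- apply_scaler(ys, as.data.frame(predict(fit, x)))
      sqrt(mean((pred_scaled - y_scaled)^2))
    }, numeric(1))
  }

  run_phase <- function(candidates, make_hidden, make_act, offset) {
    purrr::map_dfr(seq_along(candidates), function(i) {
      hid <- make_hidden(candidates[i])
      act <- make_act(candidates[i])
      rm <- cell_rmse(hid, act, offset + i)
      if (all(is.na(rm))) {
        rlang::warn(paste0("all replicates failed for candidate ",
                           candidates[i], "; cell excluded"))
      }
      tibble::tibble(
        candidate = candidates[i], activation = act,
        mean_rmse = mean(rm, na.rm = TRUE), sd_rmse = stats::sd(rm, na.rm = TRUE),
        n = sum(!is.na(rm))
      )
    })
  }
  pick_best <- function(tab) {
    ok <- tab[tab$n > 0 & is.finite(tab$mean_rmse), ]
    if (nrow(ok) == 0L) rlang::abort("every candidate failed to train")
    ok <- ok[order(ok$mean_rmse, ok$candidate), ] # tie -> smaller structure
    ok$candidate[1]
  }

  act_for_depth <- function(L) if (L <= 3) "tansig" else "relu"
  phase1 <- run_phase(layer_counts,
                      function(L) rep(phase1_neurons, L),
                      act_for_depth, 0L)
  best_layers <- pick_best(phase1)
  phase2 <- run_phase(neuron_counts,
                      function(nn) rep(nn, best_layers),
                      function(nn) act_for_depth(best_layers),
                      length(layer_counts))
  best_neurons <- pick_best(phase2)

  structure(list(
    phase1 = phase1, phase2 = phase2,
    best = list(layers = best_layers, neurons = best_neurons,
                activation = act_for_depth(best_layers)),
    reps = reps, seed = seed
  ), class = "structure_search")
}

#' @export
print.structure_search <- function(x, ...) {
  cat("<structure_search> best:", x$best$layers, "hidden layer(s) x",
      x$best$neurons, "neurons (", x$best$activation, ")\n")
  invisible(x)
}

#' Tidy a structure-search report
#'
#' @param x A `structure_search`.
#' @param ... Unused.
#' @return Tibble with `phase` (`"layers"`/`"neurons"`), `candidate`,
#'   `activation`, `mean_rmse`, `sd_rmse`, `n`.
#' @exportS3Method generics::tidy
tidy.structure_search <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$phase1, phase = "layers", .before = 1),
    dplyr::mutate(x$phase2, phase = "neurons", .before = 1)
  )
}

#' One-row summary of a structure search
#' @param x A `structure_search`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.structure_search <- function(x, ...) {
  tibble::tibble(
    best_layers = x$best$layers, best_neurons = x$best$neurons,
    activation = x$best$activation, reps = x$reps,
    cells = nrow(x$phase1) + nrow(x$phase2)
  )
}
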