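# Shared fixture builders: idealised electrode arrays and simulated worlds.

# Electrode array with all interference channels off
clean_electrodes <- function(noise_sd = 0) {
  el <- default_electrodes(noise_sd = noise_sd)
  el$selectivity <- purrr::map(el$selectivity, ~ .x * 0)
  el
}

# Deterministic drifted array: fixed per-electrode offset/gain rates
drifted_electrodes <- function(noise_sd = 0, offset = NULL, gain = NULL) {
  el <- clean_electrodes(noise_sd)
  el$offset_drift <- offset %||% seq(-2, 1.5, by = 0.5)[seq_len(nrow(el))]
  el$gain_drift <- gain %||% rep(c(2e-3, -1e-3), length.out = nrow(el))
  el
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Long truth table for joining against predictions
truth_long <- function(samples) {
  tidyr::pivot_longer(
    dplyr::select(samples, "sample_id", dplyr::all_of(PRIMARY_IONS)),
    -"sample_id", names_to = "ion", values_to = "actual_mgL"
  )
}

# Simulate a session over `samples` and return TPN predictions joined to truth
tpn_world_predictions <- function(samples, electrodes, seed = 1) {
  std <- with_background(generate_normalization_pairs())
  rd <- simulate_session(with_background(samples), electrodes, std,
                         seed = seed, ec_noise_sd = 0)
  pr <- tpn_predict(rd, reference_curves(electrodes))
  dplyr::inner_join(pr[pr$measurable, ], truth_long(samples),
                    by = c("sample_id", "ion"))
}

# thin wrapper so tests can reach the internal reference-EMF helper
standard_reference_emfs_for_test <- function(curves) {
  hybridcal:::standard_reference_emfs(curves)
}
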