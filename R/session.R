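# Measurement-session simulator: for each sample, the two-point
# normalization standards are measured under the current drift state, then
# the sample itself (optionally in replicate), then the drift advances.

#' Simulate a measurement session over a set of solutions
#'
#' Reproduces the measurement protocol of an automated ISE test stand: the
#' samples are measured in order; immediately before each sample, every
#' electrode reads the low and high normalization standards of its target
#' ion under the *current* drift state; then the sample is read by all eight
#' ISEs and the EC probe. The drift state advances by one step per sample.
#' Replicate iterations of one sample share the drift state but draw fresh
#' noise.
#'
#' @param samples Solution tibble (with counter-ion/background columns, see
#'   [with_background()]); one row per sample, mg/L columns per ion.
#' @param electrodes Electrode tibble (see [default_electrodes()],
#'   [randomize_drift()]).
#' @param standards Normalization standards tibble from
#'   [generate_normalization_pairs()], passed through [with_background()].
#'   Must contain a low/high pair for every electrode target ion.
#' @param seed Integer seed; identical seeds yield identical sessions.
#' @param start_step Drift step of the first sample (continue a campaign by
#'   passing the step where the previous sweep ended).
#' @param replicates Number of replicate iterations per sample.
#' @param ec_noise_sd Additive EC noise SD in mS/cm.
#' @param ec_exclude Ions excluded from the EC response (mechanism studies).
#' @return A tibble with one row per reading: `sample_id`, `step`, `rep`
#'   (0 for normalization readings), `electrode`, `target_ion`, `role`
#'   (`"sample"`, `"norm_low"`, `"norm_high"`), `emf_mV` (mV; for the EC row
#'   the value is in mS/cm and `electrode = target_ion = "EC"`).
#' @examples
#' des <- with_background(generate_factorial_design()[1:3, ])
#' std <- with_background(generate_normalization_pairs())
#' simulate_session(des, default_electrodes(), std, seed = 1)
#' @export
simulate_session <- function(samples, electrodes, standards, seed = 1L,
                             start_step = 0L, replicates = 1L,
                             ec_noise_sd = 0.02, ec_exclude = character()) {
  if (nrow(samples) == 0L || nrow(electrodes) == 0L) {
    rlang::abort("`samples` and `electrodes` must be non-empty")
  }
  need <- unique(electrodes$ion)
  have <- unique(standards$norm_ion)
  if (!all(need %in% have)) {
    rlang::abort(paste0("missing normalization standards for: ",
                        paste(setdiff(need, have), collapse = ", ")))
  }
  std_conc <- function(ion, which_role) {
    row <- standards[standards$norm_ion == ion &
                       standards$role == paste0("normalization-", which_role), ]
    if (nrow(row) != 1L) {
      rlang::abort(paste0("expected exactly one ", which_role,
                          " standard for ", ion))
    }
    solution_concentrations(row)
  }

  rows <- vector("list", nrow(samples))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(samples))) {
      step <- start_step + i - 1L
      sid <- samples$sample_id[i]
      conc <- solution_concentrations(samples[i, ])

      norm <- purrr::map_dfr(seq_len(nrow(electrodes)), function(e) {
        el <- electrodes[e, ]
        emf_lo <- nikolsky_emf(std_conc(el$ion, "low"), el, step)
        emf_hi <- nikolsky_emf(std_conc(el$ion, "high"), el, step)
        tibble::tibble(
          sample_id = sid, step = step, rep = 0L,
          electrode = el$electrode, target_ion = el$ion,
          role = c("norm_low", "norm_high"),
          emf_mV = c(emf_lo, emf_hi)
        )
      })

      meas <- purrr::map_dfr(seq_len(replicates), function(r) {
        ise <- purrr::map_dfr(seq_len(nrow(electrodes)), function(e) {
          el <- electrodes[e, ]
          emf <- nikolsky_emf(conc, el, step)
          tibble::tibble(
            sample_id = sid, step = step, rep = r,
            electrode = el$electrode, target_ion = el$ion,
            role = "sample",
            emf_mV = emf
          )
        })
        ec <- simulate_ec(conc, exclude = ec_exclude) +
          if (ec_noise_sd > 0) stats::rnorm(1, 0, ec_noise_sd) else 0
        dplyr::bind_rows(ise, tibble::tibble(
          sample_id = sid, step = step, rep = r,
          electrode = "EC", target_ion = "EC", role = "sample",
          emf_mV = ec
        ))
      })
      rows[[i]] <- dplyr::bind_rows(norm, meas)
    }
  })
  dplyr::bind_rows(rows)
}
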