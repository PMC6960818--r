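# The simulated sensor array: 3 NO3, 3 K and 2 Ca ion-selective electrodes.

#' Default simulated electrode array
#'
#' Builds the eight-ISE array used throughout: three NO3, three K and two Ca
#' electrodes. Replicate electrodes of one ion share a reference calibration
#' curve (slope and intercept) but have independent drift and noise streams.
#' Slopes are slightly sub-Nernstian, as real PVC-membrane electrodes are.
#'
#' Default potentiometric selectivity coefficients (log10 K_ij): Ca electrode
#' responds to Mg with -0.7; NO3 to Cl with -1.5; K to NH4 with -1.8; all
#' other same-sign interferents -4 (negligible floor). These give the array
#' the physically realistic cross-talk channels through which Mg — which has
#' no electrode of its own — leaves a signature in the Ca and EC channels.
#'
#' @param noise_sd Measurement noise SD in mV (same for all electrodes).
#' @param ca_mg_logk log10 selectivity of the Ca electrode towards Mg; set to
#'   `-Inf` to switch the Ca-Mg interference channel off.
#' @return A tibble with one row per electrode: `electrode`, `ion`, `slope`
#'   (mV/decade), `e0j` (mV), `noise_sd` (mV), `offset_drift` (mV/step),
#'   `gain_drift` (1/step) and a `selectivity` list-column of named linear
#'   K_ij coefficients.
#' @examples
#' default_electrodes()
#' @export
default_electrodes <- function(noise_sd = 0.5, ca_mg_logk = -0.7) {
  flo <- 1e-4 # 10^-4 selectivity floor for unremarkable interferents
  sel_no3 <- c(Cl = 10^-1.5, SO4 = flo)
  sel_k   <- c(NH4 = 10^-1.8, Na = flo, Ca = flo, Mg = flo)
  sel_ca  <- c(Mg = 10^ca_mg_logk, K = flo, Na = flo, NH4 = flo)
  tibble::tibble(
    electrode = c("NO3_1", "NO3_2", "NO3_3", "K_1", "K_2", "K_3", "Ca_1", "Ca_2"),
    ion       = c(rep("NO3", 3), rep("K", 3), rep("Ca", 2)),
    slope     = c(rep(-57.2, 3), rep(56.4, 3), rep(27.6, 2)),
    e0j       = c(rep(148.0, 3), rep(424.0, 3), rep(281.0, 2)),
    noise_sd  = noise_sd,
    offset_drift = 0,
    gain_drift   = 0,
    selectivity  = list(sel_no3, sel_no3, sel_no3, sel_k, sel_k, sel_k,
                        sel_ca, sel_ca)
  )
}

#' Assign random drift trajectories to an electrode array
#'
#' Draws, per electrode, a linear offset-drift rate with magnitude uniform in
#' `offset_range` mV per measurement step (random sign) and a gain-drift rate
#' uniform in `+/- gain_max` per step. The defaults emulate the drift regime
#' seen in long ISE measurement campaigns: offsets wander by 5-15 mV over a
#' ~35-step session while sensitivities stay nearly constant (about 1%).
#'
#' @param electrodes Electrode tibble from [default_electrodes()].
#' @param seed Integer seed for the drift-rate draw.
#' @param offset_range Magnitude range of the offset drift rate (mV/step).
#' @param gain_max Maximum |gain drift| per step.
#' @return The electrode tibble with `offset_drift` and `gain_drift` filled in.
#' @export
randomize_drift <- function(electrodes, seed,
                            offset_range = c(0.15, 0.45),
                            gain_max = 3e-4) {
  n <- nrow(electrodes)
  withr::with_seed(seed, {
    electrodes$offset_drift <- sample(c(-1, 1), n, replace = TRUE) *
      stats::runif(n, offset_range[1], offset_range[2])
    electrodes$gain_drift <- stats::runif(n, -gain_max, gain_max)
  })
  electrodes
}

#' Reference calibration curves of an electrode array
#'
#' Extracts the per-electrode reference curves (slope, intercept) used by the
#' TPN method — the analogue of calibration parameters determined once in a
#' previous characterisation of the membranes.
#'
#' @param electrodes Electrode tibble.
#' @return Tibble with `electrode`, `ion`, `slope`, `e0j`.
#' @export
reference_curves <- function(electrodes) {
  dplyr::select(electrodes, "electrode", "ion", "slope", "e0j")
}
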