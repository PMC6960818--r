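# Simplified Nernst response model, its Nikolsky-Eisenman extension,
# and inversion from EMF back to concentration.

#' Ideal (simplified Nernst) electrode response
#'
#' EMF = E0J + S * log10(a), where `E0J` lumps the standard and
#' liquid-junction potentials and `S` is the Nernstian slope in mV/decade
#' (ideally `59.16 / z` at 25 degrees C).
#'
#' @param activity Activity of the response ion in mol/L (> 0, vectorised).
#' @param slope Nernstian slope S in mV/decade.
#' @param e0j Combined intercept E_O + E_J in mV.
#' @return EMF in mV.
#' @examples
#' ideal_emf(1e-3, slope = 59.16, e0j = 0)
#' @export
ideal_emf <- function(activity, slope, e0j = 0) {
  stopifnot(is.numeric(activity), is.numeric(slope), is.numeric(e0j))
  if (any(!is.finite(activity)) || any(activity <= 0)) {
    rlang::abort("`activity` must be finite and > 0 (log-linear response)")
  }
  e0j + slope * log10(activity)
}

#' Invert the Nernst model: EMF to concentration
#'
#' Solves `emf = e0j + S log10(a)` for the activity and converts it to mg/L
#' using the ion's molar mass (ideal-solution assumption: activity equals
#' molar concentration). Always defined and strictly monotone in `emf`.
#'
#' @param emf Corrected EMF in mV (vectorised).
#' @param slope Reference slope S in mV/decade.
#' @param e0j Reference intercept E_O + E_J in mV.
#' @param ion Ion name (for the mg/L conversion).
#' @return Predicted concentration in mg/L.
#' @examples
#' invert_nernst(ideal_emf(1e-3, 59.16, 120), 59.16, 120, "K")
#' @export
invert_nernst <- function(emf, slope, e0j, ion) {
  stopifnot(is.numeric(emf), is.finite(slope), slope != 0, is.finite(e0j))
  molar_to_mgL(10^((emf - e0j) / slope), ion)
}

#' Fit a reference calibration curve from standard readings
#'
#' Ordinary least-squares fit of EMF (mV) against log10(activity). With
#' exactly two distinct standards the fit is the exact two-point interpolant.
#'
#' @param conc_M Known molar concentrations (mol/L) of the standards.
#' @param emf_mV Measured EMFs (mV), same length.
#' @param electrode,ion Optional identifiers carried into the result.
#' @return A one-row tibble with columns `electrode`, `ion`, `slope` (mV/decade)
#'   and `e0j` (mV).
#' @examples
#' fit_reference_curve(c(1, 10), c(0, 59.16))
#' @export
fit_reference_curve <- function(conc_M, emf_mV, electrode = NA_character_,
                                ion = NA_character_) {
  stopifnot(length(conc_M) == length(emf_mV), length(conc_M) >= 2)
  if (any(conc_M <= 0)) rlang::abort("standard concentrations must be > 0")
  lx <- log10(conc_M)
  if (max(lx) - min(lx) < 1e-12) {
    rlang::abort("standards have duplicate concentrations: fit is singular")
  }
  fit <- stats::lm(emf_mV ~ lx)
  tibble::tibble(
    electrode = electrode, ion = ion,
    slope = unname(stats::coef(fit)[2]),
    e0j   = unname(stats::coef(fit)[1])
  )
}

#' Nikolsky-Eisenman response of one electrode to a mixed solution
#'
#' Extends the simplified Nernst model with cross-ion interference, session
#' drift and measurement noise:
#'
#' EMF = g(s) * S * log10( a_i + sum_j K_ij * a_j^(z_i/z_j) ) + E0J + d(s) + eps
#'
#' where `g(s) = 1 + gain_drift * s` and `d(s) = offset_drift * s` are the
#' gain and offset drift trajectories at measurement step `s`, `K_ij` are the
#' potentiometric selectivity coefficients, and `eps ~ N(0, noise_sd)` is
#' drawn from the current RNG stream. With all `K_ij = 0`, zero drift and
#' zero noise the response reduces exactly to [ideal_emf()].
#'
#' @param conc Named numeric vector of concentrations in mg/L (all ions in the
#'   solution; missing ions are treated as absent).
#' @param electrode One row of an electrode table (see [default_electrodes()]).
#' @param step Measurement step index (drift state), 0 = undrifted.
#' @param noise If `FALSE`, suppress the noise draw (no RNG use).
#' @return EMF in mV (length 1).
#' @export
nikolsky_emf <- function(conc, electrode, step = 0, noise = TRUE) {
  stopifnot(is.numeric(conc), !is.null(names(conc)))
  if (nrow(electrode) != 1L) rlang::abort("`electrode` must be a single row")
  reg <- ion_registry()
  target <- electrode$ion
  zi <- ion_row(target)$charge
  a_i <- mgL_to_molar(if (target %in% names(conc)) conc[[target]] else 0, target)

  ksel <- electrode$selectivity[[1]]
  interf <- 0
  if (length(ksel)) {
    for (j in names(ksel)) {
      if (!j %in% names(conc) || conc[[j]] <= 0 || ksel[[j]] <= 0) next
      zj <- ion_row(j)$charge
      a_j <- mgL_to_molar(conc[[j]], j)
      interf <- interf + ksel[[j]] * a_j^(zi / zj)
    }
  }
  arg <- a_i + interf
  if (!is.finite(arg) || arg <= 0) {
    rlang::abort("log argument non-positive: empty solution for this electrode")
  }
  g <- 1 + electrode$gain_drift * step
  d <- electrode$offset_drift * step
  eps <- if (noise && electrode$noise_sd > 0) {
    stats::rnorm(1, 0, electrode$noise_sd)
  } else 0
  g * electrode$slope * log10(arg) + electrode$e0j + d + eps
}
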