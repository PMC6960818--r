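# Ion registry and unit conversions.

#' Nernstian slope constant at 25 degrees C
#'
#' The ideal slope of an ion-selective electrode is `59.16 / z` mV per decade
#' change in activity, where `z` is the signed charge number of the response
#' ion.
#'
#' @format A numeric scalar, in mV/decade.
#' @export
NERNST_SLOPE_25C <- 59.16

#' The four nutrient ions predicted by the sensor array
#' @format Character vector of ion names.
#' @export
PRIMARY_IONS <- c("NO3", "K", "Ca", "Mg")

#' Ion registry
#'
#' Properties of the ions handled by the simulator and calibration code: the
#' four primary nutrient ions (NO3, K, Ca, Mg) and the background ions that
#' occur in hydroponic matrices (NH4, Cl, SO4, Na). `lambda0` is the limiting
#' equivalent ionic conductivity used by [simulate_ec()].
#'
#' @return A tibble with columns `ion`, `charge` (signed integer),
#'   `molar_mass` (g/mol) and `lambda0` (S cm^2/eq).
#' @examples
#' ion_registry()
#' @export
ion_registry <- function() {
  tibble::tribble(
    ~ion,  ~charge, ~molar_mass, ~lambda0,
    "NO3", -1L,      62.004,     71.42,
    "K",    1L,      39.098,     73.48,
    "Ca",   2L,      40.078,     59.47,
    "Mg",   2L,      24.305,     53.05,
    "NH4",  1L,      18.039,     73.50,
    "Cl",  -1L,      35.453,     76.31,
    "SO4", -2L,      96.06,      79.80,
    "Na",   1L,      22.990,     50.08
  )
}

ion_row <- function(ion) {
  reg <- ion_registry()
  hit <- reg[reg$ion == ion, ]
  if (nrow(hit) != 1L) {
    rlang::abort(paste0("unknown ion name: '", ion, "'"))
  }
  hit
}

#' Convert a mass concentration to molar concentration
#'
#' @param conc_mgL Concentration in mg/L (vectorised, must be finite and >= 0).
#' @param ion Single ion name present in [ion_registry()].
#' @return Molar concentration in mol/L.
#' @examples
#' mgL_to_molar(62.004, "NO3") # 1e-3 mol/L
#' @export
mgL_to_molar <- function(conc_mgL, ion) {
  stopifnot(is.numeric(conc_mgL), all(is.finite(conc_mgL)), all(conc_mgL >= 0))
  conc_mgL / (1000 * ion_row(ion)$molar_mass)
}

#' Convert a molar concentration back to mg/L
#'
#' @param conc_M Concentration in mol/L.
#' @param ion Single ion name present in [ion_registry()].
#' @return Concentration in mg/L.
#' @export
molar_to_mgL <- function(conc_M, ion) {
  stopifnot(is.numeric(conc_M))
  conc_M * 1000 * ion_row(ion)$molar_mass
}

#' Single-ion activity coefficient (extended Debye-Hueckel)
#'
#' Optional correction from concentration to activity. The calibration code
#' assumes ideal solutions (activity == molar concentration) by default, since
#' the simplified Nernst model is stated in terms of activity without an
#' ionic-strength model; this helper is provided for users who want to
#' propagate a non-ideal correction through the simulator.
#'
#' Uses the Davies form: log10(gamma) = -A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I)
#' with A = 0.509 at 25 degrees C.
#'
#' @param ionic_strength Ionic strength in mol/L.
#' @param charge Signed charge number of the ion.
#' @return The dimensionless activity coefficient gamma (<= 1 for I > 0).
#' @export
activity_coefficient <- function(ionic_strength, charge) {
  stopifnot(ionic_strength >= 0)
  sI <- sqrt(ionic_strength)
  10^(-0.509 * charge^2 * (sI / (1 + sI) - 0.3 * ionic_strength))
}
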