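# Solution matrices: counter-ions from the preparation salts, background
# electrolyte, and the bulk electrical-conductivity model.

#' Default background electrolyte (mg/L)
#'
#' Fixed Na/Cl/SO4/NH4 background approximating a half-strength Hoagland
#' nutrient base mixed 1:1 with tap water — the matrix in which training
#' mixtures are prepared so they resemble real hydroponic solutions.
#'
#' @return Named numeric vector of mg/L.
#' @export
default_background <- function() {
  c(Na = 25, Cl = 30, SO4 = 60, NH4 = 5)
}

#' Add counter-ions and background matrix to solution tables
#'
#' The four nutrients are added as salts — ammonium nitrate, potassium
#' sulfate, calcium chloride and magnesium sulfate — so every mixture also
#' carries the stoichiometric counter-ions: NH4 (1 mol per mol NO3), SO4
#' (1 mol per mol Mg + 0.5 mol per mol K) and Cl (2 mol per mol Ca).
#' Training and field solutions additionally receive the fixed base
#' background; single-salt normalization standards are prepared in pure
#' water and get counter-ions only.
#'
#' @param samples Solution tibble with `role` and mg/L columns NO3, K, Ca, Mg.
#' @param base Named mg/L vector for the background matrix
#'   (see [default_background()]).
#' @param mg_sulfate If `FALSE`, magnesium is added without its sulfate
#'   counter-ion (used to switch the EC channel of Mg off in simulation
#'   studies of the Mg-inference mechanism).
#' @return The input tibble with `NH4`, `SO4`, `Cl`, `Na` columns appended
#'   (added to any pre-existing values).
#' @export
with_background <- function(samples, base = default_background(),
                            mg_sulfate = TRUE) {
  stopifnot(all(PRIMARY_IONS %in% names(samples)))
  mol <- function(ion) mgL_to_molar(samples[[ion]], ion)
  nh4 <- molar_to_mgL(mol("NO3"), "NH4")
  so4 <- molar_to_mgL(0.5 * mol("K") + if (mg_sulfate) mol("Mg") else 0, "SO4")
  cl  <- molar_to_mgL(2 * mol("Ca"), "Cl")
  in_water <- grepl("^normalization", samples$role)
  add_base <- function(ion) ifelse(in_water, 0, base[[ion]])
  grab <- function(nm) if (nm %in% names(samples)) samples[[nm]] else 0
  samples$NH4 <- grab("NH4") + nh4 + add_base("NH4")
  samples$SO4 <- grab("SO4") + so4 + add_base("SO4")
  samples$Cl  <- grab("Cl") + cl + add_base("Cl")
  samples$Na  <- grab("Na") + add_base("Na")
  samples
}

#' Extract one sample's full concentration vector
#'
#' @param sample One row of a solution tibble.
#' @return Named numeric vector (mg/L) over the ions present as columns.
#' @keywords internal
solution_concentrations <- function(sample) {
  ions <- intersect(ion_registry()$ion, names(sample))
  v <- as.numeric(sample[1, ions])
  names(v) <- ions
  v
}

#' Simulated bulk electrical conductivity of a solution
#'
#' Kohlrausch's law of independent migration at infinite dilution:
#' EC (mS/cm) = sum over ions of lambda0_i * c_eq,i, with c_eq in eq/L and
#' lambda0 the limiting equivalent conductivity from [ion_registry()].
#' Additive in the ions by construction; 0 for pure water.
#'
#' @param conc Named numeric vector of concentrations in mg/L.
#' @param exclude Ion names whose contribution is suppressed.
#' @return EC in mS/cm.
#' @examples
#' simulate_ec(c(K = 39.098, NO3 = 62.004)) # 1e-3 eq/L KNO3
#' @export
simulate_ec <- function(conc, exclude = character()) {
  stopifnot(is.numeric(conc), !is.null(names(conc)))
  ec <- 0
  for (ion in setdiff(names(conc), exclude)) {
    row <- ion_row(ion)
    c_eq <- mgL_to_molar(conc[[ion]], ion) * abs(row$charge)
    ec <- ec + row$lambda0 * c_eq
  }
  ec
}
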