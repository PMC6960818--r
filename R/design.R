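# Solution design: fractional factorial training mixtures, two-point
# normalization standards and random field samples.

#' Default 3-level design concentrations (mg/L)
#'
#' Low / mid / high levels for the four nutrient factors. The low and high
#' levels double as the two-point normalization standards.
#'
#' @return Named list of ascending 3-vectors (mg/L).
#' @export
default_design_levels <- function() {
  list(
    NO3 = c(100, 550, 1000),
    K   = c(30, 165, 300),
    Ca  = c(24, 132, 240),
    Mg  = c(10, 55, 100)
  )
}

#' Generate the 3-level fractional factorial training design
#'
#' Builds a regular one-third fraction of the 3^4 factorial: 27 mixtures of
#' the four nutrient factors, each factor level occurring 9 times, with
#' main-effect orthogonality (every level pair of any two factors occurs
#' exactly 3 times). The fraction uses the generator D = A + B + C (mod 3).
#' `fraction = "full"` returns all 81 runs.
#'
#' @param levels Named list of exactly 4 factors, each with 3 ascending
#'   levels in mg/L (see [default_design_levels()]).
#' @param fraction `"one-third"` (27 runs, default) or `"full"` (81 runs).
#' @return A tibble with `sample_id`, `role = "training"` and one mg/L column
#'   per factor.
#' @examples
#' generate_factorial_design()
#' @export
generate_factorial_design <- function(levels = default_design_levels(),
                                      fraction = c("one-third", "full")) {
  fraction <- match.arg(fraction)
  if (length(levels) != 4L) {
    rlang::abort("the design requires exactly 4 factors")
  }
  ok <- vapply(levels, function(v) length(v) == 3L && !is.unsorted(v) &&
                 all(is.finite(v)) && all(v >= 0), logical(1))
  if (!all(ok)) {
    rlang::abort("every factor needs 3 finite ascending non-negative levels")
  }
  idx <- expand.grid(A = 0:2, B = 0:2, C = 0:2, KEEP.OUT.ATTRS = FALSE)
  if (fraction == "full") {
    idx <- expand.grid(A = 0:2, B = 0:2, C = 0:2, D = 0:2,
                       KEEP.OUT.ATTRS = FALSE)
  } else {
    idx$D <- (idx$A + idx$B + idx$C) %% 3
  }
  nm <- names(levels)
  out <- tibble::tibble(
    sample_id = sprintf("train_%02d", seq_len(nrow(idx))),
    role = "training"
  )
  for (k in seq_along(nm)) {
    out[[nm[k]]] <- levels[[nm[k]]][idx[[k]] + 1L]
  }
  out
}

#' Generate the two-point normalization standards
#'
#' One low and one high single-salt standard per primary ion, at the lowest
#' and highest design levels (defaults: NO3 100/1000, K 30/300, Ca 24/240,
#' Mg 10/100 mg/L). Only the target ion is present; the other primary ions
#' are zero.
#'
#' @param levels Named list of 3-level design concentrations.
#' @return A tibble of 8 samples with roles `"normalization-low"` /
#'   `"normalization-high"` and mg/L columns for the four primary ions.
#' @examples
#' generate_normalization_pairs()
#' @export
generate_normalization_pairs <- function(levels = default_design_levels()) {
  ions <- names(levels)
  rows <- purrr::map_dfr(ions, function(ion) {
    tibble::tibble(
      sample_id = paste0("norm_", ion, "_", c("low", "high")),
      role = paste0("normalization-", c("low", "high")),
      norm_ion = ion,
      value = c(levels[[ion]][1], levels[[ion]][3])
    )
  })
  for (ion in ions) {
    rows[[ion]] <- ifelse(rows$norm_ion == ion, rows$value, 0)
  }
  dplyr::select(rows, "sample_id", "role", "norm_ion",
                dplyr::all_of(ions))
}

#' Draw random field samples inside the calibrated ranges
#'
#' Emulates real hydroponic samples for held-out evaluation: concentrations
#' are drawn uniformly between the lowest and highest design level of each
#' nutrient, independently per ion.
#'
#' @param n Number of samples.
#' @param levels Named list of 3-level design concentrations; only the
#'   extremes are used.
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `role = "field"` and mg/L columns.
#' @export
generate_field_samples <- function(n = 8, levels = default_design_levels(),
                                   seed = 1L) {
  out <- tibble::tibble(
    sample_id = sprintf("field_%02d", seq_len(n)),
    role = "field"
  )
  withr::with_seed(seed, {
    for (ion in names(levels)) {
      rng <- range(levels[[ion]])
      out[[ion]] <- stats::runif(n, rng[1], rng[2])
    }
  })
  out
}
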