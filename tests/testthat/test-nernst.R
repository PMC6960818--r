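# Unit bridge, Nernst response, Nikolsky extension and inversion.

test_that("mg/L to molar conversion matches molar masses", {
  expect_identical(mgL_to_molar(0, "NO3"), 0)
  expect_equal(mgL_to_molar(62.004, "NO3"), 1e-3)
  expect_equal(mgL_to_molar(39.098, "K"), 1e-3)
  expect_equal(molar_to_mgL(mgL_to_molar(123.4, "Ca"), "Ca"), 123.4)
  expect_error(mgL_to_molar(1, "Xe"), "unknown ion")
  expect_error(mgL_to_molar(-1, "K"))
})

test_that("ideal EMF follows the simplified log-linear response", {
  expect_equal(ideal_emf(1, slope = 59.16, e0j = 0), 0)
  expect_equal(ideal_emf(10, slope = 59.16, e0j = 0), 59.16)
  # anion electrode: negative slope
  expect_equal(ideal_emf(10, slope = -59.16, e0j = 100), 40.84)
  expect_error(ideal_emf(0, 59.16, 0), "activity")
  expect_error(ideal_emf(-1, 59.16, 0), "activity")
})

test_that("Nikolsky response reduces to the ideal response without interference, drift or noise", {
  el <- clean_electrodes()
  withr::with_seed(11, {
    for (i in 1:100) {
      conc <- c(NO3 = runif(1, 50, 1200), K = runif(1, 10, 400),
                Ca = runif(1, 10, 300), Mg = runif(1, 5, 120))
      e <- sample(nrow(el), 1)
      ion <- el$ion[e]
      expect_equal(
        nikolsky_emf(conc, el[e, ], step = 3, noise = FALSE),
        ideal_emf(mgL_to_molar(conc[[ion]], ion), el$slope[e], el$e0j[e]),
        tolerance = 1e-12
      )
    }
  })
})

test_that("zero-concentration interferents leave the response untouched", {
  el <- default_electrodes(noise_sd = 0) # selectivities on
  conc <- c(K = 100, NH4 = 0, Na = 0, Ca = 0, Mg = 0)
  expect_equal(nikolsky_emf(conc, el[el$electrode == "K_1", ], noise = FALSE),
               ideal_emf(mgL_to_molar(100, "K"),
                         el$slope[el$electrode == "K_1"],
                         el$e0j[el$electrode == "K_1"]))
})

test_that("interference adds the selectivity-weighted activity inside the log", {
  el <- default_electrodes(noise_sd = 0)[4, ] # a K electrode
  el$slope <- 59.16; el$e0j <- 0
  el$selectivity <- list(c(NH4 = 0.1))
  conc <- c(K = molar_to_mgL(1e-3, "K"), NH4 = molar_to_mgL(1e-3, "NH4"))
  expect_equal(nikolsky_emf(conc, el, noise = FALSE),
               59.16 * log10(1.1e-3), tolerance = 1e-12)
})

test_that("EMF is monotone in the target concentration with the charge-appropriate sign", {
  el <- clean_electrodes()
  conc_grid <- seq(20, 800, length.out = 12)
  k_emf <- vapply(conc_grid, function(cc)
    nikolsky_emf(c(K = cc), el[el$electrode == "K_1", ], noise = FALSE),
    numeric(1))
  no3_emf <- vapply(conc_grid, function(cc)
    nikolsky_emf(c(NO3 = cc), el[el$electrode == "NO3_1", ], noise = FALSE),
    numeric(1))
  expect_true(all(diff(k_emf) > 0))   # cation: increasing
  expect_true(all(diff(no3_emf) < 0)) # anion (S < 0): decreasing
})

test_that("Nernst inversion is the exact inverse of the ideal response", {
  expect_equal(invert_nernst(120, slope = 59.16, e0j = 120, ion = "K"),
               molar_to_mgL(1, "K"))
  expect_equal(invert_nernst(120 + 59.16, 59.16, 120, "K"),
               molar_to_mgL(10, "K"))
  withr::with_seed(7, {
    for (ion in PRIMARY_IONS) {
      conc <- runif(100, 1, 2000)
      slope <- NERNST_SLOPE_25C / ion_registry()$charge[
        ion_registry()$ion == ion]
      emf <- ideal_emf(mgL_to_molar(conc, ion), slope, e0j = 77)
      back <- invert_nernst(emf, slope, 77, ion)
      expect_equal(back, conc, tolerance = 1e-9)
    }
  })
})

test_that("reference-curve fitting recovers slope and intercept", {
  cv <- fit_reference_curve(c(1, 10), c(0, 59.16))
  expect_equal(cv$slope, 59.16)
  expect_equal(cv$e0j, 0, tolerance = 1e-12)
  # 5 noiseless points
  conc <- c(1e-4, 1e-3, 1e-2, 0.05, 0.5)
  cv2 <- fit_reference_curve(conc, ideal_emf(conc, -57.2, 148))
  expect_equal(cv2$slope, -57.2, tolerance = 1e-9)
  expect_equal(cv2$e0j, 148, tolerance = 1e-9)
  expect_error(fit_reference_curve(c(1e-3, 1e-3), c(0, 1)), "duplicate")
  expect_error(fit_reference_curve(1e-3, 5))
})
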