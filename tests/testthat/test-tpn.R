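# Two-point normalization: identity, exact drift cancellation, inversion,
# interference bias, degenerate inputs.

test_that("TPN is the identity when the measured pair equals the reference pair", {
  withr::with_seed(5, {
    for (i in 1:20) {
      lo <- runif(1, -100, 100); hi <- lo + runif(1, 20, 200)
      emf <- runif(1, -200, 300)
      expect_equal(tpn_correct(emf, lo, hi, lo, hi), emf, tolerance = 1e-12)
    }
  })
})

test_that("the high standard maps exactly onto the reference point", {
  expect_equal(tpn_correct(212, ref_low = 100, ref_high = 160,
                           meas_low = 95, meas_high = 212), 160)
})

test_that("TPN cancels arbitrary gain and offset drift exactly (algebraic identity)", {
  withr::with_seed(21, {
    for (i in 1:200) {
      g <- runif(1, 0.7, 1.3)
      d <- runif(1, -30, 30)
      ref_low <- runif(1, -50, 50)
      ref_high <- ref_low + runif(1, 30, 150) * sample(c(-1, 1), 1)
      true_emf <- runif(1, min(ref_low, ref_high), max(ref_low, ref_high))
      corrected <- tpn_correct(g * true_emf + d,
                               ref_low, ref_high,
                               g * ref_low + d, g * ref_high + d)
      expect_equal(corrected, true_emf, tolerance = 1e-9)
    }
  })
})

test_that("TPN correction is affine in the input EMF for a fixed context", {
  f <- function(e) tpn_correct(e, 0, 100, 10, 120)
  e <- c(-40, 0, 35, 80, 200)
  slope <- (f(1) - f(0))
  expect_equal(f(e), f(0) + slope * e, tolerance = 1e-12)
})

test_that("a dead electrode (equal standard readings) is an error", {
  expect_error(tpn_correct(50, 0, 100, 60, 60), "dead electrode")
})

test_that("TPN predictions recover true concentrations on a drifted noiseless session", {
  des <- with_background(generate_factorial_design())
  std <- with_background(generate_normalization_pairs())
  el <- drifted_electrodes()
  rd <- simulate_session(des, el, std, seed = 5, ec_noise_sd = 0)
  m <- tpn_world_predictions(generate_factorial_design(), el, seed = 5)
  expect_gt(nrow(m), 0)
  expect_equal(m$predicted_mgL, m$actual_mgL, tolerance = 1e-6)
})

test_that("TPN-corrected EMFs equal the undrifted session's EMFs", {
  des <- with_background(generate_factorial_design()[1:10, ])
  std <- with_background(generate_normalization_pairs())
  el <- drifted_electrodes()
  el0 <- clean_electrodes()
  rd <- simulate_session(des, el, std, seed = 5, ec_noise_sd = 0)
  rd0 <- simulate_session(des, el0, std, seed = 5, ec_noise_sd = 0)
  cor <- tpn_correct_readings(rd, reference_curves(el))
  ise <- cor$electrode != "EC"
  raw0 <- rd0[rd0$role == "sample", ]
  expect_equal(cor$emf_mV[ise], raw0$emf_mV[raw0$electrode != "EC"],
               tolerance = 1e-9)
})

test_that("Mg is reported as not measurable by the TPN method", {
  des <- with_background(generate_factorial_design()[1:2, ])
  std <- with_background(generate_normalization_pairs())
  el <- clean_electrodes()
  rd <- simulate_session(des, el, std, seed = 1, ec_noise_sd = 0)
  pr <- tpn_predict(rd, reference_curves(el))
  mg <- pr[pr$ion == "Mg", ]
  expect_equal(nrow(mg), 2)
  expect_true(all(!mg$measurable))
  expect_true(all(is.na(mg$predicted_mgL)))
  expect_true(all(pr$measurable[pr$ion != "Mg"]))
})

test_that("interference biases TPN towards over-prediction of the interfered ion", {
  # Ca electrode with Mg selectivity on: a_Mg adds inside the log, so the
  # inverted Ca concentration must exceed the truth.
  des <- tibble::tibble(sample_id = "s1", role = "field",
                        NO3 = 500, K = 150, Ca = 40, Mg = 100)
  std <- with_background(generate_normalization_pairs())
  el <- default_electrodes(noise_sd = 0) # interference on
  rd <- simulate_session(with_background(des), el, std, seed = 1,
                         ec_noise_sd = 0)
  pr <- tpn_predict(rd, reference_curves(el))
  expect_gt(pr$predicted_mgL[pr$ion == "Ca"], 40 * 1.2)
  # and in a Mg-free solution the Ca prediction is unbiased
  des0 <- dplyr::mutate(des, Mg = 0)
  rd0 <- simulate_session(with_background(des0), el, std, seed = 1,
                          ec_noise_sd = 0)
  pr0 <- tpn_predict(rd0, reference_curves(el))
  expect_equal(pr0$predicted_mgL[pr0$ion == "Ca"], 40, tolerance = 1e-3)
})

test_that("excluding a dead electrode averages over the remaining replicates with a warning", {
  des <- with_background(generate_factorial_design()[1:2, ])
  std <- with_background(generate_normalization_pairs())
  el <- clean_electrodes()
  rd <- simulate_session(des, el, std, seed = 1, ec_noise_sd = 0)
  expect_warning(
    pr <- tpn_predict(rd, reference_curves(el),
                      exclude_electrodes = "NO3_3"),
    "excluding"
  )
  expect_equal(unique(pr$n_electrodes[pr$ion == "NO3"]), 2L)
  expect_equal(unique(pr$n_electrodes[pr$ion == "K"]), 3L)
})

test_that("missing normalization readings are an error", {
  des <- with_background(generate_factorial_design()[1:2, ])
  std <- with_background(generate_normalization_pairs())
  el <- clean_electrodes()
  rd <- simulate_session(des, el, std, seed = 1, ec_noise_sd = 0)
  rd_broken <- rd[!(rd$role == "norm_low" & rd$electrode == "K_1"), ]
  expect_error(tpn_predict(rd_broken, reference_curves(el)),
               "missing normalization pair")
})
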