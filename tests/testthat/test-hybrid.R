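# Hybrid pipeline: training-table assembly and the three-method runner.

drift_free_world <- function(noise_sd = 0, seed = 3, n = 6,
                             interference = FALSE) {
  des <- generate_factorial_design()[seq_len(n), ]
  std <- with_background(generate_normalization_pairs())
  el <- if (interference) default_electrodes(noise_sd = noise_sd) else
    clean_electrodes(noise_sd)
  rd <- simulate_session(with_background(des), el, std, seed = seed,
                         ec_noise_sd = 0)
  list(des = des, std = std, el = el, rd = rd)
}

test_that("without drift the raw and TPN-corrected training tables coincide", {
  w <- drift_free_world(n = 15) # enough design rows that every factor varies
  raw <- build_training_table(w$rd, w$des, "ann")
  cor <- build_training_table(w$rd, w$des, "tpn-ann",
                              curves = reference_curves(w$el))
  expect_equal(as.matrix(cor$x), as.matrix(raw$x), tolerance = 1e-9)
  expect_identical(raw$meta, cor$meta)
  expect_equal(raw$y, cor$y)
  # hence identical networks from the same seed
  f1 <- ann_train(raw$x, raw$y, hidden = 6, seed = 21, max_epochs = 15,
                  validation = 0)
  f2 <- ann_train(cor$x, cor$y, hidden = 6, seed = 21, max_epochs = 15,
                  validation = 0)
  expect_equal(f1$net$w, f2$net$w, tolerance = 1e-9)
})

test_that("TPN correction restores the drift-free training table", {
  des <- generate_factorial_design()[1:8, ]
  std <- with_background(generate_normalization_pairs())
  el0 <- clean_electrodes()
  eld <- drifted_electrodes()
  rd0 <- simulate_session(with_background(des), el0, std, seed = 9,
                          ec_noise_sd = 0)
  rdd <- simulate_session(with_background(des), eld, std, seed = 9,
                          ec_noise_sd = 0)
  x0 <- build_training_table(rd0, des, "ann")$x
  xc <- build_training_table(rdd, des, "tpn-ann",
                             curves = reference_curves(eld))$x
  expect_equal(as.matrix(xc), as.matrix(x0), tolerance = 1e-6)
})

test_that("EC is passed through identically by both table layouts", {
  w <- drift_free_world(noise_sd = 0.5)
  raw <- build_training_table(w$rd, w$des, "ann")
  cor <- build_training_table(w$rd, w$des, "tpn-ann",
                              curves = reference_curves(w$el))
  expect_identical(raw$x$EC, cor$x$EC)
})

test_that("the table builder validates its inputs", {
  w <- drift_free_world()
  expect_error(build_training_table(w$rd, w$des, "tpn-ann"), "curves")
  no_norm <- w$rd[w$rd$role == "sample", ]
  expect_error(build_training_table(no_norm, w$des, "tpn-ann",
                                    curves = reference_curves(w$el)),
               "normalization")
  broken <- w$rd[w$rd$electrode != "K_2", ]
  expect_error(build_training_table(broken, w$des, "ann"), "K_2")
  expect_error(build_training_table(w$rd, w$des[-1, ], "ann"),
               "missing some sample_ids")
})

test_that("run_methods returns aligned predictions for all three methods", {
  des <- generate_factorial_design()
  std <- with_background(generate_normalization_pairs())
  el <- clean_electrodes(noise_sd = 0.2)
  train_rd <- simulate_session(with_background(des), el, std, seed = 31,
                               replicates = 2)
  test_des <- generate_field_samples(4, seed = 32)
  test_rd <- simulate_session(with_background(test_des), el, std, seed = 33,
                              start_step = 27, replicates = 2)
  res <- run_methods(train_rd, des, test_rd, seed = 34, max_epochs = 60)
  p <- res$predictions
  expect_setequal(unique(p$method), c("TPN", "ANN", "TPN-ANN"))
  # the TPN method never emits a measurable Mg prediction
  expect_true(all(!p$measurable[p$method == "TPN" & p$ion == "Mg"]))
  expect_true(all(p$measurable[p$method != "TPN"]))
  expect_named(res$models, c("ann", "tpn-ann"))
  # in a drift-free, interference-free world the methods agree within noise
  wide <- p[p$measurable & p$ion != "Mg", ] |>
    dplyr::group_by(.data$sample_id, .data$ion, .data$method) |>
    dplyr::summarise(pred = mean(.data$predicted_mgL), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "method", values_from = "pred")
  expect_equal(wide$`TPN-ANN`, wide$TPN, tolerance = 0.15)
  expect_equal(wide$ANN, wide$TPN, tolerance = 0.15)
})

test_that("method subsets run alone", {
  des <- generate_factorial_design()[1:5, ]
  std <- with_background(generate_normalization_pairs())
  el <- clean_electrodes(0.2)
  rd <- simulate_session(with_background(des), el, std, seed = 1)
  res <- run_methods(rd, des, rd, methods = "tpn")
  expect_equal(unique(res$predictions$method), "TPN")
  expect_length(res$models, 0)
})
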