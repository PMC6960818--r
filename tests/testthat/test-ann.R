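# Min-max scaling, forward propagation, Jacobian, LM training.

test_that("min-max scaling satisfies the boundary identities exactly", {
  x <- data.frame(a = c(2, 6, 10), b = c(-1, 0, 3))
  sc <- fit_scaler(x)
  s <- apply_scaler(sc, x)
  expect_equal(s[1, "a"][[1]], 0)
  expect_equal(s[3, "a"][[1]], 1)
  expect_equal(apply_scaler(sc, data.frame(a = 6, b = 1))[1, "a"][[1]], 0.5)
  # out-of-range values are not clipped
  expect_gt(apply_scaler(sc, data.frame(a = 14, b = 0))[1, "a"][[1]], 1)
  expect_lt(apply_scaler(sc, data.frame(a = 0, b = 0))[1, "a"][[1]], 0)
})

test_that("scaler round-trip is exact to machine precision", {
  withr::with_seed(3, {
    x <- matrix(runif(60, -5, 20), 20, 3)
    colnames(x) <- c("p", "q", "r")
    sc <- fit_scaler(x)
    expect_equal(invert_scaler(sc, apply_scaler(sc, x)), x,
                 tolerance = 1e-14)
    y <- matrix(runif(9), 3, 3); colnames(y) <- colnames(x)
    expect_equal(apply_scaler(sc, invert_scaler(sc, y)), y,
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("constant features are rejected when fitting a scaler", {
  expect_error(fit_scaler(data.frame(a = c(1, 1, 1), b = 1:3)), "constant")
})

test_that("forward propagation matches hand computations", {
  # all weights zero: output equals output-layer biases
  net <- new_network(c(9, 5, 4), "tansig", seed = 1)
  net$w <- purrr::map(net$w, ~ .x * 0)
  net$b[[2]] <- c(1, -2, 0.5, 0)
  out <- ann_forward(net, matrix(runif(18), 2, 9))
  expect_equal(out, matrix(rep(c(1, -2, 0.5, 0), each = 2), 2, 4))

  # single linear hidden neuron: y = w2 * (w1 x + b1) + b2
  net2 <- new_network(c(1, 1, 1), "linear", seed = 1)
  net2$w[[1]][] <- 2; net2$b[[1]] <- 1; net2$w[[2]][] <- 3; net2$b[[2]] <- -4
  expect_equal(ann_forward(net2, matrix(c(0, 1, 2), 3, 1)),
               matrix(3 * (2 * c(0, 1, 2) + 1) - 4, 3, 1))
})

test_that("tansig saturates to +/- 1 for large pre-activations", {
  net <- new_network(c(1, 1, 1), "tansig", seed = 1)
  net$w[[1]][] <- 50; net$b[[1]] <- 0; net$w[[2]][] <- 1; net$b[[2]] <- 0
  expect_equal(ann_forward(net, matrix(c(1, -1), 2, 1)),
               matrix(c(1, -1), 2, 1), tolerance = 1e-12)
})

test_that("dimension mismatches are rejected", {
  net <- new_network(c(9, 5, 4), seed = 1)
  expect_error(ann_forward(net, matrix(0, 2, 8)), "expects 9")
  expect_error(train_lm(net, matrix(0, 3, 9), matrix(0, 3, 5)),
               "output layer")
})

test_that("the analytic Jacobian matches central finite differences", {
  for (act in c("tansig", "relu")) {
    net <- new_network(c(3, 5, 4, 2), act, seed = 42)
    # nonzero biases keep ReLU pre-activations off the exact kink, where a
    # central difference straddles the non-differentiable point
    net$b <- withr::with_seed(43, lapply(net$b, function(b)
      stats::runif(length(b), 0.05, 0.3)))
    x <- withr::with_seed(8, matrix(runif(12, -1, 1), 4, 3))
    J <- hybridcal:::ann_jacobian(net, x)
    th <- hybridcal:::flatten_params(net)
    h <- 1e-6
    J_fd <- matrix(0, nrow(J), ncol(J))
    for (p in seq_along(th)) {
      tp <- th; tp[p] <- th[p] + h
      tm <- th; tm[p] <- th[p] - h
      J_fd[, p] <- as.vector(
        ann_forward(hybridcal:::set_params(net, tp), x) -
          ann_forward(hybridcal:::set_params(net, tm), x)) / (2 * h)
    }
    expect_lt(max(abs(J - J_fd)) / max(abs(J)), 1e-5)
  }
})

test_that("LM training recovers a noiseless affine map to high precision", {
  withr::with_seed(1, {
    x <- matrix(runif(27 * 9), 27, 9); colnames(x) <- paste0("x", 1:9)
    a <- matrix(runif(36, -1, 1), 9, 4)
    y <- x %*% a + rep(runif(4), each = 27); colnames(y) <- paste0("y", 1:4)
  })
  fit <- ann_train(x, y, hidden = 14, seed = 3, max_epochs = 300,
                   validation = 0)
  y_sc <- apply_scaler(fit$y_scaler, y)
  p_sc <- apply_scaler(fit$y_scaler, as.matrix(predict(fit, x)))
  expect_lt(sqrt(mean((p_sc - y_sc)^2)), 1e-3)
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("training is reproducible from the seed", {
  withr::with_seed(2, {
    x <- matrix(runif(30 * 9), 30, 9); colnames(x) <- paste0("x", 1:9)
    y <- x[, 1:4] + matrix(rnorm(120, 0, 0.05), 30, 4)
    colnames(y) <- paste0("y", 1:4)
  })
  f1 <- ann_train(x, y, hidden = 8, seed = 11, max_epochs = 40)
  f2 <- ann_train(x, y, hidden = 8, seed = 11, max_epochs = 40)
  expect_identical(f1$net$w, f2$net$w)
  expect_identical(f1$trace, f2$trace)
  f3 <- ann_train(x, y, hidden = 8, seed = 12, max_epochs = 40)
  expect_false(identical(f1$net$w, f3$net$w))
})

test_that("the network fits the noiseless 27-run design within 5% of each range", {
  des <- generate_factorial_design()
  std <- with_background(generate_normalization_pairs())
  el <- default_electrodes(noise_sd = 0) # interference on, no drift/noise
  rd <- simulate_session(with_background(des), el, std, seed = 4,
                         ec_noise_sd = 0)
  tab <- build_training_table(rd, des, "ann")
  fit <- ann_train(tab$x, tab$y, hidden = 14, seed = 5, max_epochs = 400,
                   validation = 0)
  pred <- predict(fit, tab$x)
  for (ion in PRIMARY_IONS) {
    rng <- diff(range(default_design_levels()[[ion]]))
    expect_lt(rmse(pred[[ion]], tab$y[[ion]]), 0.05 * rng)
  }
  # Mg is predicted even though no Mg electrode exists
  expect_true("Mg" %in% names(pred))
})

test_that("early stopping on held-out rows restores the best-validation weights", {
  withr::with_seed(6, {
    x <- matrix(runif(40 * 9), 40, 9); colnames(x) <- paste0("x", 1:9)
    y <- x[, 1:4]^2 + matrix(rnorm(160, 0, 0.1), 40, 4)
    colnames(y) <- paste0("y", 1:4)
  })
  fit <- ann_train(x, y, hidden = 14, seed = 2, max_epochs = 200,
                   validation = 0.25, patience = 10)
  expect_gt(fit$n_validation, 0)
  expect_equal(length(fit$val_trace), length(fit$trace))
  # the returned weights attain the minimum of the validation trace
  expect_equal(min(fit$val_trace), fit$val_trace[which.min(fit$val_trace)])
})

test_that("tidy and glance expose the fitted structure", {
  withr::with_seed(2, {
    x <- matrix(runif(12 * 9), 12, 9); colnames(x) <- paste0("x", 1:9)
    y <- x[, 1:4]; colnames(y) <- paste0("y", 1:4)
  })
  fit <- ann_train(x, y, hidden = 6, seed = 1, max_epochs = 10,
                   validation = 0)
  td <- tidy(fit)
  expect_equal(sum(td$term == "weight"), 9 * 6 + 6 * 4)
  expect_equal(sum(td$term == "bias"), 6 + 4)
  gl <- glance(fit)
  expect_equal(gl$inputs, 9L)
  expect_equal(gl$outputs, 4L)
  expect_equal(gl$n_params, 9 * 6 + 6 + 6 * 4 + 4)
})
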