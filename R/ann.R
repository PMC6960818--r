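# Feed-forward network with Levenberg-Marquardt training.
#
# The network maps the 9 scaled sensor signals (8 ISE EMFs + EC) to the 4
# scaled nutrient concentrations. Hidden layers use tansig (tanh) or ReLU;
# the output layer is linear. Training minimises the sum of squared errors
# over all outputs with damped Gauss-Newton steps, using an analytic
# backpropagated Jacobian of the network outputs with respect to the
# weights.

act_fun <- function(tag) {
  switch(tag,
    tansig = tanh,
    relu   = function(z) pmax(z, 0),
    linear = identity,
    rlang::abort(paste0("unknown activation: ", tag))
  )
}

act_deriv <- function(tag, z, a) {
  switch(tag,
    tansig = 1 - a^2,
    relu   = (z > 0) * 1,
    linear = array(1, dim(z)),
    rlang::abort(paste0("unknown activation: ", tag))
  )
}

#' Create a feed-forward network with seeded random weights
#'
#' Weights are initialised uniformly in `[-0.5, 0.5] / sqrt(fan_in)`,
#' a small symmetric init suited to tanh units; biases start at 0.
#'
#' @param layers Integer vector of layer sizes, input first (e.g.
#'   `c(9, 14, 4)`).
#' @param activation Hidden-layer activation, `"tansig"` or `"relu"`; the
#'   output layer is always linear.
#' @param seed Integer seed for the weight draw.
#' @return An object of class `ise_network`.
#' @export
new_network <- function(layers, activation = "tansig", seed = 1L) {
  stopifnot(length(layers) >= 2, all(layers >= 1))
  L <- length(layers) - 1L
  acts <- c(rep(activation, L - 1L), "linear")
  w <- vector("list", L)
  b <- vector("list", L)
  withr::with_seed(seed, {
    for (l in seq_len(L)) {
      p <- layers[l]; q <- layers[l + 1L]
      w[[l]] <- matrix(stats::runif(p * q, -0.5, 0.5) / sqrt(p), p, q)
      b[[l]] <- rep(0, q)
    }
  })
  structure(list(layers = as.integer(layers), w = w, b = b, acts = acts),
            class = "ise_network")
}

#' Forward propagation
#'
#' Standard layered affine-then-activation propagation; deterministic.
#'
#' @param net An `ise_network`.
#' @param x Matrix of inputs, one row per sample, `net$layers[1]` columns.
#' @param cache Keep per-layer pre-activations/activations (for training)?
#' @return Output matrix (rows = samples), or with `cache = TRUE` a list
#'   `(output, z, a)`.
#' @export
ann_forward <- function(net, x, cache = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != net$layers[1]) {
    rlang::abort(sprintf("input has %d columns, network expects %d",
                         ncol(x), net$layers[1]))
  }
  L <- length(net$w)
  a <- vector("list", L + 1L); z <- vector("list", L)
  a[[1]] <- x
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% net$w[[l]], 2, net$b[[l]], "+")
    a[[l + 1L]] <- act_fun(net$acts[l])(z[[l]])
  }
  if (cache) list(output = a[[L + 1L]], z = z, a = a) else a[[L + 1L]]
}

# Flatten all weights and biases into one parameter vector
# (layer by layer: column-major W, then b).
flatten_params <- function(net) {
  unlist(purrr::map2(net$w, net$b, ~ c(as.vector(.x), .y)), use.names = FALSE)
}

set_params <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$w)) {
    p <- nrow(net$w[[l]]); q <- ncol(net$w[[l]])
    net$w[[l]] <- matrix(theta[pos + seq_len(p * q)], p, q)
    pos <- pos + p * q
    net$b[[l]] <- theta[pos + seq_len(q)]
    pos <- pos + q
  }
  net
}

# Jacobian of the stacked network outputs with respect to all parameters,
# by reverse-mode accumulation (one backward sweep per output unit).
# Row order: output k = 1..K in blocks of N samples. Column order matches
# flatten_params().
ann_jacobian <- function(net, x) {
  fw <- ann_forward(net, x, cache = TRUE)
  n <- nrow(fw$output); K <- ncol(fw$output)
  L <- length(net$w)
  P <- length(flatten_params(net))
  # column offsets of each layer's W and b blocks
  off <- integer(L); pos <- 0L
  for (l in seq_len(L)) {
    off[l] <- pos
    pos <- pos + nrow(net$w[[l]]) * ncol(net$w[[l]]) + ncol(net$w[[l]])
  }
  J <- matrix(0, n * K, P)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * n + seq_len(n)
    D <- matrix(0, n, K); D[, k] <- 1 # linear output layer
    for (l in rev(seq_len(L))) {
      p <- nrow(net$w[[l]]); q <- ncol(net$w[[l]])
      aprev <- fw$a[[l]]
      # d out_k / d W_l[i, j] = aprev[, i] * D[, j]
      J[rows, off[l] + seq_len(p * q)] <-
        aprev[, rep(seq_len(p), q), drop = FALSE] *
        D[, rep(seq_len(q), each = p), drop = FALSE]
      J[rows, off[l] + p * q + seq_len(q)] <- D
      if (l > 1L) {
        D <- (D %*% t(net$w[[l]])) *
          act_deriv(net$acts[l - 1L], fw$z[[l - 1L]], fw$a[[l]])
      }
    }
  }
  J
}

#' Train a network with the Levenberg-Marquardt algorithm
#'
#' Damped Gauss-Newton minimisation of the sum of squared errors over all
#' outputs. Each epoch solves `(J'J + lambda I) delta = J' r` with the
#' analytic Jacobian `J`; a step is accepted only if it decreases the SSE
#' (the damping is divided by 10 on acceptance and multiplied by 10 on
#' rejection), so the trace of accepted losses is non-increasing. The
#' conventional learning rate of 0.01 enters as the initial damping
#' `lambda0`.
#'
#' @param net An `ise_network`.
#' @param x,y Matrices of scaled inputs and targets (rows = samples).
#' @param max_epochs Maximum accepted iterations.
#' @param lambda0 Initial damping parameter.
#' @param tol Relative SSE decrease below which training stops.
#' @param lambda_max Damping overflow bound (training stops above it).
#' @param val_x,val_y Optional validation matrices: after every accepted
#'   step the validation SSE is evaluated, the best-validation weights are
#'   retained, and training stops once the validation loss has failed to
#'   improve for `patience` consecutive accepted steps (early stopping, the
#'   standard overfitting guard for LM-trained networks).
#' @param patience Consecutive non-improving validation checks tolerated.
#' @return List: `net` (trained; best-validation weights when validation
#'   data were supplied), `trace` (accepted training SSE per epoch,
#'   starting with the initial SSE), `val_trace`, `epochs`, `converged`,
#'   `final_sse`.
#' @export
train_lm <- function(net, x, y, max_epochs = 1000, lambda0 = 0.01,
                     tol = 1e-9, lambda_max = 1e10,
                     val_x = NULL, val_y = NULL, patience = 6L) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  if (ncol(y) != net$layers[length(net$layers)]) {
    rlang::abort("target width does not match the network's output layer")
  }
  use_val <- !is.null(val_x) && !is.null(val_y) && nrow(as.matrix(val_x)) > 0
  if (use_val) { val_x <- as.matrix(val_x); val_y <- as.matrix(val_y) }
  n <- nrow(x)
  theta <- flatten_params(net)
  resid_vec <- function(th) {
    out <- ann_forward(set_params(net, th), x)
    as.vector(y - out) # column-major: output blocks of n, matches J rows
  }
  val_sse <- function(th) {
    sum((val_y - ann_forward(set_params(net, th), val_x))^2)
  }
  r <- resid_vec(theta)
  sse <- sum(r^2)
  if (!is.finite(sse)) rlang::abort("non-finite loss at initialisation")
  lambda <- lambda0
  trace <- sse
  val_trace <- if (use_val) val_sse(theta) else numeric()
  best_val <- if (use_val) val_trace else Inf
  best_theta <- theta
  val_fails <- 0L
  converged <- FALSE
  epoch <- 0L
  while (epoch < max_epochs) {
    J <- ann_jacobian(set_params(net, theta), x)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    accepted <- FALSE
    while (!accepted && lambda <= lambda_max) {
      delta <- tryCatch(
        solve(JtJ + diag(lambda, ncol(JtJ)), g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        th_new <- theta + as.vector(delta)
        r_new <- resid_vec(th_new)
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          accepted <- TRUE
          theta <- th_new; r <- r_new
          rel <- (sse - sse_new) / max(sse, .Machine$double.xmin)
          sse <- sse_new
          lambda <- max(lambda / 10, 1e-12)
          epoch <- epoch + 1L
          trace <- c(trace, sse)
          if (use_val) {
            v <- val_sse(theta)
            val_trace <- c(val_trace, v)
            if (v < best_val) {
              best_val <- v; best_theta <- theta; val_fails <- 0L
            } else {
              val_fails <- val_fails + 1L
              if (val_fails >= patience) converged <- TRUE
            }
          }
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged) break
  }
  if (use_val) theta <- best_theta
  net <- set_params(net, theta)
  list(net = net, trace = trace, val_trace = val_trace, epochs = epoch,
       converged = converged || epoch >= max_epochs,
       final_sse = if (use_val) sum(resid_vec(theta)^2) else sse)
}

#' Fit the sensor-array network on raw signal and composition tables
#'
#' Convenience wrapper implementing the full calibration fit: min-max scale
#' the 9 input signals and the 4 target concentrations to `[0, 1]`
#' (inputs and outputs each get their own scaler so the four ions contribute
#' comparably to the joint SSE), build a seeded network and train it with
#' [train_lm()].
#'
#' @param x Data frame/matrix of input signals (one row per measurement,
#'   columns in the fixed order NO3_1..3, K_1..3, Ca_1..2, EC).
#' @param y Data frame/matrix of known concentrations (mg/L), columns
#'   NO3, K, Ca, Mg.
#' @param hidden Integer vector of hidden-layer sizes (default one layer of
#'   14 neurons, the structure selected by the search on the default data).
#' @param activation `"tansig"`, `"relu"`, or `NULL` to choose by depth
#'   (tansig up to 3 hidden layers, ReLU for deeper nets, where tanh
#'   saturation starves the gradient).
#' @param seed Integer seed (weight initialisation and validation split).
#' @param max_epochs,lambda0,tol Passed to [train_lm()].
#' @param validation Fraction of rows held out for early stopping (0 to
#'   disable; also disabled automatically below 10 rows). The held-out rows
#'   monitor generalisation so training stops before the network starts
#'   interpolating measurement noise.
#' @param patience Early-stopping patience (see [train_lm()]).
#' @param groups Optional vector (one entry per row) identifying replicate
#'   measurements of the same solution; the validation split then holds out
#'   whole solutions, so near-duplicate replicates cannot leak between the
#'   training and validation sets.
#' @param val_rows Optional explicit row indices to hold out for validation
#'   (overrides `validation`/`groups`). Used by the campaign runner to hold
#'   out one full replicate iteration: every solution stays in the training
#'   set while the held-out iteration's fresh noise flags the onset of
#'   noise interpolation.
#' @param restarts Number of seeded weight initialisations to train; the
#'   fit with the lowest validation SSE (training SSE when no validation
#'   set exists) is returned. Gauss-Newton descent on a small non-convex
#'   loss is sensitive to its starting point, so a handful of restarts
#'   guards against poor local minima — the same reason the structure
#'   search trains every candidate in triplicate.
#' @return An object of class `ann_fit`: the trained network, both scalers
#'   and training metadata. Use [predict.ann_fit()] to get mg/L predictions.
#' @export
ann_train <- function(x, y, hidden = 14, activation = NULL, seed = 1L,
                      max_epochs = 1000, lambda0 = 0.01, tol = 1e-9,
                      validation = 0.2, patience = 6L, groups = NULL,
                      val_rows = NULL, restarts = 1L) {
  if (restarts > 1L) {
    init_seeds <- withr::with_seed(seed,
                                   sample.int(.Machine$integer.max - 1L,
                                              restarts))
    fits <- lapply(init_seeds, function(s) {
      ann_train(x, y, hidden = hidden, activation = activation, seed = s,
                max_epochs = max_epochs, lambda0 = lambda0, tol = tol,
                validation = validation, patience = patience,
                groups = groups, val_rows = val_rows, restarts = 1L)
    })
    score <- vapply(fits, function(f) {
      if (length(f$val_trace)) min(f$val_trace) else f$final_sse
    }, numeric(1))
    best <- fits[[which.min(score)]]
    best$restarts <- restarts
    best$master_seed <- seed
    return(best)
  }
  x <- as.data.frame(x); y <- as.data.frame(y)
  if (is.null(activation)) {
    activation <- if (length(hidden) <= 3) "tansig" else "relu"
  }
  xs <- fit_scaler(x); ys <- fit_scaler(y)
  net <- new_network(c(ncol(x), hidden, ncol(y)), activation, seed)
  x_sc <- apply_scaler(xs, x); y_sc <- apply_scaler(ys, y)
  n <- nrow(x_sc)
  use_val <- validation > 0 && n >= 10
  idx <- integer()
  if (!is.null(val_rows)) {
    stopifnot(all(val_rows >= 1), all(val_rows <= n))
    idx <- unique(as.integer(val_rows))
  } else if (use_val) {
    if (is.null(groups)) {
      n_val <- floor(validation * n)
      if (n_val >= 1) idx <- withr::with_seed(seed, sample.int(n, n_val))
    } else {
      stopifnot(length(groups) == n)
      g <- unique(groups)
      n_g <- floor(validation * length(g))
      if (n_g >= 1) {
        held <- withr::with_seed(seed, sample(g, n_g))
        idx <- which(groups %in% held)
      }
    }
  }
  n_val <- length(idx)
  val_x <- NULL; val_y <- NULL
  if (n_val >= 1) {
    val_x <- x_sc[idx, , drop = FALSE]; val_y <- y_sc[idx, , drop = FALSE]
    x_sc <- x_sc[-idx, , drop = FALSE]; y_sc <- y_sc[-idx, , drop = FALSE]
  }
  fit <- train_lm(net, x_sc, y_sc,
                  max_epochs = max_epochs, lambda0 = lambda0, tol = tol,
                  val_x = val_x, val_y = val_y, patience = patience)
  structure(list(
    net = fit$net, x_scaler = xs, y_scaler = ys,
    trace = fit$trace, val_trace = fit$val_trace,
    epochs = fit$epochs, converged = fit$converged,
    final_sse = fit$final_sse, hidden = hidden, activation = activation,
    seed = seed, n_validation = n_val
  ), class = "ann_fit")
}

#' Predict nutrient concentrations from raw sensor signals
#'
#' Scales the raw 9-signal inputs, propagates them through the trained
#' network and maps the scaled outputs back to mg/L.
#'
#' @param object An `ann_fit`.
#' @param newdata Data frame/matrix with the fit's input columns.
#' @param ... Unused.
#' @return A tibble with one mg/L column per predicted ion.
#' @export
predict.ann_fit <- function(object, newdata, ...) {
  xs <- apply_scaler(object$x_scaler, as.data.frame(newdata))
  out <- invert_scaler(object$y_scaler, ann_forward(object$net, xs))
  tibble::as_tibble(out)
}

#' @export
print.ann_fit <- function(x, ...) {
  cat("<ann_fit> ", paste(x$net$layers, collapse = "-"),
      " (", x$activation, "), ", x$epochs, " LM epochs, final SSE ",
      signif(x$final_sse, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy the weights of a fitted sensor-array network
#'
#' @param x An `ann_fit`.
#' @param ... Unused.
#' @return Tibble with `layer`, `term` (`"weight"`/`"bias"`), `from`, `to`,
#'   `estimate`.
#' @exportS3Method generics::tidy
tidy.ann_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$net$w), function(l) {
    w <- x$net$w[[l]]
    dplyr::bind_rows(
      tibble::tibble(
        layer = l, term = "weight",
        from = rep(seq_len(nrow(w)), ncol(w)),
        to = rep(seq_len(ncol(w)), each = nrow(w)),
        estimate = as.vector(w)
      ),
      tibble::tibble(layer = l, term = "bias", from = NA_integer_,
                     to = seq_along(x$net$b[[l]]), estimate = x$net$b[[l]])
    )
  })
}

#' One-row training summary of a fitted network
#'
#' @param x An `ann_fit`.
#' @param ... Unused.
#' @return Tibble with structure and convergence columns.
#' @exportS3Method generics::glance
glance.ann_fit <- function(x, ...) {
  tibble::tibble(
    inputs = x$net$layers[1],
    outputs = x$net$layers[length(x$net$layers)],
    hidden_layers = length(x$hidden),
    hidden_neurons = x$hidden[1],
    activation = x$activation,
    n_params = length(flatten_params(x$net)),
    epochs = x$epochs,
    converged = x$converged,
    final_sse = x$final_sse
  )
}
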