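# Min-max feature scaling: X_r = (X_s - X_min) / (X_max - X_min).

#' Fit a min-max scaler
#'
#' Records per-feature minima and maxima so that the training data map onto
#' `[0, 1]`: the minimum maps to 0, the maximum to 1, the midpoint to 0.5.
#' Test-time inputs outside the training range map outside `[0, 1]` and are
#' not clipped.
#'
#' @param x Data frame or matrix of numeric features (>= 2 distinct values
#'   per feature).
#' @return An object of class `minmax_scaler`.
#' @examples
#' sc <- fit_scaler(data.frame(a = c(0, 5, 10)))
#' apply_scaler(sc, data.frame(a = 5))
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 2)
  x_min <- apply(x, 2, min)
  x_max <- apply(x, 2, max)
  flat <- x_max - x_min <= 0
  if (any(flat)) {
    rlang::abort(paste0("constant feature(s): ",
                        paste(colnames(x)[flat], collapse = ", ")))
  }
  structure(list(features = colnames(x), x_min = x_min, x_max = x_max),
            class = "minmax_scaler")
}

#' @describeIn fit_scaler Apply a fitted scaler; returns a matrix of the
#'   rescaled features in the scaler's feature order.
#' @param scaler A fitted `minmax_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  x <- as.matrix(x)
  if (!is.null(scaler$features) && !is.null(colnames(x))) {
    miss <- setdiff(scaler$features, colnames(x))
    if (length(miss)) {
      rlang::abort(paste0("missing feature(s): ", paste(miss, collapse = ", ")))
    }
    x <- x[, scaler$features, drop = FALSE]
  }
  sweep(sweep(x, 2, scaler$x_min), 2, scaler$x_max - scaler$x_min, "/")
}

#' @describeIn fit_scaler Invert the scaling, mapping `[0, 1]` features back
#'   to original units (exact round-trip to machine precision).
#' @param x_scaled Matrix of scaled features.
#' @export
invert_scaler <- function(scaler, x_scaled) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  x_scaled <- as.matrix(x_scaled)
  out <- sweep(sweep(x_scaled, 2, scaler$x_max - scaler$x_min, "*"),
               2, scaler$x_min, "+")
  colnames(out) <- scaler$features
  out
}
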