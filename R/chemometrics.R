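#' Fit a PLS1 calibration model
#'
#' Mean-centred univariate partial least squares by the NIPALS algorithm
#' (closed-form per factor for a single response): for each factor the
#' weight vector is `w = X'y / ||X'y||`, scores `t = X w`, loadings
#' `p = X't / t't`, `q = y't / t't`, followed by deflation of `X` and `y`.
#' The regression vector `B = W (P'W)^{-1} q` assembles the model so that
#' `predict(x) = y_mean + (x - x_mean) B`.
#'
#' @param X Numeric matrix, n samples x p bands.
#' @param y Numeric response of length n (e.g. days of drought).
#' @param n_factors Number of latent factors, `1 <= n_factors <= min(n-1, p)`.
#' @param wavelengths Optional band grid carried for interpretation.
#' @return A `pls_model`.
#' @export
fit_pls <- function(X, y, n_factors, wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("X and y must be finite")
  if (stats::var(y) < 1e-24) stop("response has zero variance")
  n_factors <- as.integer(n_factors)
  if (n_factors < 1 || n_factors > min(n - 1L, p))
    stop("n_factors must be in [1, min(n-1, p)] = [1, ", min(n - 1L, p), "]")
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  W <- matrix(0, p, n_factors); P <- matrix(0, p, n_factors)
  qv <- numeric(n_factors)
  for (a in seq_len(n_factors)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {  # X residual orthogonal to y residual: stop early
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      qv <- qv[seq_len(a - 1L)]
      n_factors <- a - 1L
      break
    }
    w <- w / nw
    tt <- as.vector(Xc %*% w)
    t2 <- sum(tt^2)
    pp <- as.vector(crossprod(Xc, tt)) / t2
    qq <- sum(yc * tt) / t2
    Xc <- Xc - tcrossprod(tt, pp)
    yc <- yc - qq * tt
    W[, a] <- w; P[, a] <- pp; qv[a] <- qq
  }
  if (n_factors < 1) stop("no usable PLS factor (X uncorrelated with y)")
  B <- W %*% solve(crossprod(P, W), qv)
  structure(list(n_factors = n_factors, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = qv,
                 regression_vector = as.vector(B),
                 wavelengths = wavelengths, n_train = n),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param X New data, n x p on the training band grid.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$x_mean))
    stop("band grid mismatch: model has ", length(object$x_mean),
         " bands, data has ", ncol(X))
  if (!is.null(object$wavelengths) && !is.null(colnames(X))) {
    wl <- suppressWarnings(as.numeric(colnames(X)))
    if (!anyNA(wl) && any(abs(wl - object$wavelengths) > 1e-6))
      stop("band grid mismatch: wavelengths differ from training grid")
  }
  as.vector(object$y_mean +
              sweep(X, 2, object$x_mean) %*% object$regression_vector)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_factors, " factor(s), ", length(x$x_mean),
      " bands, trained on ", x$n_train, " samples\n", sep = "")
  invisible(x)
}

#' Leave-one-group-out cross-validation for PLS factor selection
#'
#' Each group (one leaf's replicate spectra from one measurement occasion)
#' is left out in turn, honouring the replicate structure: no fold's
#' training set ever contains a row whose group is in its test set. For
#' every factor count `1..max_factors` the standard error of
#' cross-validation is `SECV(a) = sqrt(mean((yhat_cv - y)^2))`; the chosen
#' number of factors is the argmin of the SECV curve, ties broken toward
#' fewer factors. The full-data model at the chosen dimension gives SEC and
#' the calibration statistics.
#'
#' @param X Numeric matrix n x p.
#' @param y Numeric response.
#' @param group_ids Vector of fold labels (one fold per unique value;
#'   folds are visited in sorted label order, so the SECV curve is
#'   deterministic).
#' @param max_factors Upper bound of the factor search (default 10; capped
#'   by the smallest training fold).
#' @param wavelengths Optional band grid passed to the final model.
#' @return A `cv_report`: `secv_curve`, `n_factors`, `secv`, `sec`, `r2cv`,
#'   `r2cal`, `r2cv_press` (1 - PRESS/SStot variant), `cv_predictions`,
#'   `model` (the full-data `pls_model` at the chosen dimension).
#' @export
grouped_cv <- function(X, y, group_ids, max_factors = 10L,
                       wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(group_ids) != n) stop("group_ids must have one entry per row")
  folds <- sort(unique(as.character(group_ids)))
  if (length(folds) < 2) stop("a single group would leave no training data")
  gchr <- as.character(group_ids)
  min_train <- n - max(table(gchr))
  A <- min(as.integer(max_factors), min_train - 1L, ncol(X))
  if (A < 1) stop("not enough training rows for even one factor")
  preds <- matrix(NA_real_, n, A)
  for (f in folds) {
    test <- gchr == f
    m <- fit_pls(X[!test, , drop = FALSE], y[!test], A)
    preds[test, seq_len(m$n_factors)] <-
      pls_predict_per_factor(m, X[test, , drop = FALSE])
    if (m$n_factors < A)  # degenerate fold: reuse deepest available factor
      preds[test, seq.int(m$n_factors + 1L, A)] <- preds[test, m$n_factors]
  }
  secv_curve <- sqrt(colMeans((preds - y)^2))
  chosen <- which.min(secv_curve)  # first minimum = fewest factors on ties
  model <- fit_pls(X, y, chosen, wavelengths = wavelengths)
  yhat_cal <- predict(model, X)
  yhat_cv <- preds[, chosen]
  sstot <- sum((y - mean(y))^2)
  structure(list(
    secv_curve = secv_curve,
    n_factors = as.integer(chosen),
    secv = secv_curve[chosen],
    sec = sqrt(mean((yhat_cal - y)^2)),
    r2cv = stats::cor(yhat_cv, y)^2,
    r2cal = stats::cor(yhat_cal, y)^2,
    r2cv_press = 1 - sum((yhat_cv - y)^2) / sstot,
    cv_predictions = yhat_cv,
    folds = folds,
    model = model), class = "cv_report")
}

# per-factor predictions via sequential score computation
pls_predict_per_factor <- function(m, X) {
  Xc <- sweep(as.matrix(X), 2, m$x_mean)
  out <- matrix(0, nrow(Xc), m$n_factors)
  acc <- rep(m$y_mean, nrow(Xc))
  for (a in seq_len(m$n_factors)) {
    tt <- as.vector(Xc %*% m$weights[, a])
    acc <- acc + tt * m$y_loadings[a]
    Xc <- Xc - tcrossprod(tt, m$x_loadings[, a])
    out[, a] <- acc
  }
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> factors = ", x$n_factors,
      ", SECV = ", signif(x$secv, 4),
      ", R2cv = ", signif(x$r2cv, 4),
      ", SEC = ", signif(x$sec, 4),
      ", R2cal = ", signif(x$r2cal, 4), "\n", sep = "")
  invisible(x)
}

#' Correlation spectrum
#'
#' Pearson correlation between the response and each band, a standard PLS
#' interpretation plot: bands whose absorbance tracks the response show
#' |r| near 1.
#'
#' @param X Numeric matrix n x p.
#' @param y Numeric response (non-constant).
#' @return Numeric vector of per-band correlations in `[-1, 1]`;
#'   zero-variance bands get `r = 0` with a warning.
#' @export
correlation_spectrum <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (stats::var(y) < 1e-24) stop("response has zero variance")
  sds <- apply(X, 2, stats::sd)
  zero <- sds < 1e-14
  r <- rep(0, ncol(X))
  if (any(!zero))
    r[!zero] <- as.vector(stats::cor(X[, !zero, drop = FALSE], y))
  if (any(zero))
    warning(sum(zero), " zero-variance band(s); correlation set to 0")
  r
}

#' Most influential bands of a PLS model
#'
#' Ranks bands by the magnitude of the regression-vector coefficient and
#' returns the top `top_k` with their signed coefficients.
#'
#' @param m A `pls_model` fitted with a `wavelengths` grid.
#' @param top_k Number of bands to return (clipped to the number of bands
#'   with a warning).
#' @return A tibble `wavelength`, `coefficient`, ordered by decreasing
#'   |coefficient|.
#' @export
important_bands <- function(m, top_k = 5L) {
  if (!inherits(m, "pls_model")) stop("expected a pls_model")
  b <- m$regression_vector
  wl <- if (!is.null(m$wavelengths)) m$wavelengths else seq_along(b)
  if (all(b == 0)) {
    warning("all regression coefficients are zero")
    return(tibble::tibble(wavelength = numeric(0), coefficient = numeric(0)))
  }
  if (top_k > length(b)) {
    warning("top_k exceeds the number of bands; returning all")
    top_k <- length(b)
  }
  ord <- order(abs(b), decreasing = TRUE)[seq_len(top_k)]
  tibble::tibble(wavelength = wl[ord], coefficient = b[ord])
}
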