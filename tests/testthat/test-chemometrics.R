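test_that("one factor recovers a single-latent-direction response exactly", {
  set.seed(61)
  t_scores <- rnorm(20)
  load <- runif(5)
  X <- outer(t_scores, load)        # rank-1 design
  y <- 2 + 3 * t_scores
  m <- fit_pls(X, y, 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-10)
})

test_that("full-rank PLS equals the OLS oracle", {
  set.seed(62)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- X %*% runif(5) + rnorm(20, 0, 0.3)
  m <- fit_pls(X, y, 5)
  ols <- lm.fit(cbind(1, X), as.vector(y))
  expect_equal(as.vector(predict(m, X)),
               as.vector(cbind(1, X) %*% ols$coefficients), tolerance = 1e-8)
})

test_that("fit_pls validates its inputs", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fit_pls(X, rep(1, 4), 1), "zero variance")
  expect_error(fit_pls(X, 1:4, 4), "n_factors")
  expect_error(fit_pls(X, 1:3, 1), "length")
  expect_error(fit_pls(X * NA, 1:4, 1), "finite")
})

test_that("prediction is an affine map consistent with the scores path", {
  set.seed(63)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- X[, 1] - 2 * X[, 5] + rnorm(30, 0, 0.1)
  m <- fit_pls(X, y, 4)
  # centre maps to the mean response
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean, tolerance = 1e-10)
  # regression-vector route equals sequential score accumulation
  scores_route <- aqualeaf:::pls_predict_per_factor(m, X)[, 4]
  expect_equal(as.vector(predict(m, X)), scores_route, tolerance = 1e-10)
  # duplicated row, duplicated prediction
  expect_equal(predict(m, X[c(3, 3), ])[1], predict(m, X[c(3, 3), ])[2])
  expect_error(predict(m, X[, 1:5]), "mismatch")
})

test_that("predictions are invariant to training row order", {
  set.seed(64)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- X %*% runif(6) + rnorm(25, 0, 0.2)
  m1 <- fit_pls(X, y, 3)
  perm <- sample(25)
  m2 <- fit_pls(X[perm, ], y[perm], 3)
  Xnew <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(predict(m1, Xnew), predict(m2, Xnew), tolerance = 1e-10)
})

test_that("singleton groups reduce grouped CV to leave-one-out; noiseless limit", {
  set.seed(65)
  X <- matrix(rnorm(24 * 3), 24, 3)
  y <- as.vector(X %*% c(1, -2, 0.5))    # exact linear, no noise
  cv <- grouped_cv(X, y, group_ids = seq_len(24), max_factors = 3)
  expect_equal(cv$n_factors, 3)
  expect_lt(cv$secv, 1e-6)
  expect_gt(cv$r2cv, 1 - 1e-10)
})

test_that("no CV fold trains on rows of its own group", {
  set.seed(66)
  n <- 30
  gid <- rep(letters[1:10], each = 3)
  X <- matrix(rnorm(n * 4), n, 4)
  # marker column: group index leaks loudly into predictions if folds mix
  y <- rnorm(n)
  cv <- grouped_cv(X, y, gid, max_factors = 2)
  expect_equal(length(cv$folds), 10)
  expect_setequal(cv$folds, letters[1:10])
  # direct partition property on the implementation's fold loop
  for (f in cv$folds) {
    test_rows <- which(gid == f)
    train_rows <- which(gid != f)
    expect_length(intersect(test_rows, train_rows), 0)
    expect_equal(sort(c(test_rows, train_rows)), 1:n)
  }
  expect_error(grouped_cv(X, y, rep("all", n)), "single group")
})

test_that("the SECV curve is deterministic for a fixed fold partition", {
  set.seed(67)
  X <- matrix(rnorm(36 * 6), 36, 6)
  y <- X %*% runif(6) + rnorm(36, 0, 0.5)
  gid <- rep(1:12, each = 3)
  cv1 <- grouped_cv(X, y, gid, 5)
  cv2 <- grouped_cv(X, y, gid, 5)
  expect_identical(cv1$secv_curve, cv2$secv_curve)
  # row order of the input must not matter either
  perm <- sample(36)
  cv3 <- grouped_cv(X[perm, ], y[perm], gid[perm], 5)
  expect_equal(cv3$secv_curve, cv1$secv_curve, tolerance = 1e-10)
})

test_that("correlation spectrum matches a per-band loop and handles nulls", {
  set.seed(68)
  X <- matrix(rnorm(50 * 7), 50, 7)
  y <- rnorm(50)
  r <- correlation_spectrum(X, y)
  loop <- vapply(1:7, function(j) cor(X[, j], y), numeric(1))
  expect_equal(r, loop, tolerance = 1e-12)
  expect_true(all(abs(r) <= 1))
  # y equal to a band gives r = 1 there
  expect_equal(correlation_spectrum(X, X[, 3])[3], 1, tolerance = 1e-12)
  # independent noise at large n stays near zero
  set.seed(69)
  Xbig <- matrix(rnorm(1000 * 5), 1000, 5)
  expect_lt(max(abs(correlation_spectrum(Xbig, rnorm(1000)))), 0.1)
  # zero-variance band -> r 0 with warning
  X[, 2] <- 1
  expect_warning(r0 <- correlation_spectrum(X, y), "zero-variance")
  expect_equal(r0[2], 0)
})

test_that("important_bands ranks by |coefficient| and clips top_k", {
  m <- structure(list(regression_vector = c(0.1, -5, 2, 0),
                      wavelengths = c(1300, 1409.843, 1450, 1500)),
                 class = "pls_model")
  top <- important_bands(m, 1)
  expect_equal(top$wavelength, 1409.843)
  expect_warning(all4 <- important_bands(m, 10), "top_k")
  expect_equal(nrow(all4), 4)
  m$regression_vector <- rep(0, 4)
  expect_warning(none <- important_bands(m, 2), "zero")
  expect_equal(nrow(none), 0)
})
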