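test_that("SG second derivative is exact on polynomials", {
  wl <- seq_len(40)  # unit-step grid
  quad <- matrix(3 * wl^2, 1)
  lin <- matrix(2 + 5 * wl, 1)
  s <- spectra_set(wl, rbind(quad, lin))
  d2 <- sg_derivative(s, sg_config(window = 11, polyorder = 2, deriv = 2,
                                   scale = "per_index"))
  expect_equal(d2$absorbance[1, ], rep(6, n_bands(d2)), tolerance = 1e-9)
  expect_equal(d2$absorbance[2, ], rep(0, n_bands(d2)), tolerance = 1e-9)
  # edges truncated: half-window dropped on each side
  expect_equal(n_bands(d2), 40 - 10)
  expect_equal(d2$wavelengths, wl[6:35])
})

test_that("SG derivative matches a per-point polynomial least-squares fit", {
  set.seed(3)
  p <- 30
  wl <- seq_len(p)
  x <- rnorm(p)
  s <- spectra_set(wl, matrix(x, 1))
  win <- 7; ord <- 3; h <- 3
  d2 <- sg_derivative(s, sg_config(win, ord, 2))
  oracle <- vapply(seq(h + 1, p - h), function(i) {
    idx <- (i - h):(i + h)
    fit <- lm(x[idx] ~ poly(idx - i, ord, raw = TRUE))
    2 * coef(fit)[[3]]  # second derivative of the local fit at the centre
  }, numeric(1))
  expect_equal(d2$absorbance[1, ], oracle, tolerance = 1e-8)
})

test_that("SG filter is linear and agrees with the signal package kernel", {
  set.seed(4)
  s <- toy_spectra(2, 40)
  cfg <- sg_config(11, 2, 2)
  lin_comb <- spectra_set(s$wavelengths,
                          matrix(2 * s$absorbance[1, ] - 3 * s$absorbance[2, ], 1))
  d_comb <- sg_derivative(lin_comb, cfg)$absorbance[1, ]
  d_each <- sg_derivative(s, cfg)$absorbance
  expect_equal(d_comb, 2 * d_each[1, ] - 3 * d_each[2, ], tolerance = 1e-12)

  skip_if_not_installed("signal")
  k_ref <- signal::sgolay(p = 2, n = 11, m = 2)[6, ]
  expect_equal(aqualeaf:::sg_kernel(11, 2, 2), as.vector(k_ref),
               tolerance = 1e-10)
})

test_that("SG config validation rejects bad windows", {
  expect_error(sg_config(window = 8), "odd")
  expect_error(sg_config(window = 3), "odd|>= 5")
  expect_error(sg_config(window = 7, polyorder = 7), "polyorder")
  expect_error(sg_config(deriv = 3, polyorder = 2), "deriv")
  s <- toy_spectra(1, 9)
  expect_error(sg_derivative(s, sg_config(window = 11)), "window")
})

test_that("per-nm scaling divides by the squared grid step", {
  wl <- seq(1300, by = 6.2, length.out = 30)
  s <- spectra_set(wl, matrix(rnorm(30), 1))
  a <- sg_derivative(s, sg_config(scale = "per_index"))$absorbance
  b <- sg_derivative(s, sg_config(scale = "per_nm"))$absorbance
  expect_equal(b, a / 6.2^2, tolerance = 1e-12)
})

test_that("MSC maps affine distortions of the reference back to it", {
  set.seed(5)
  ref <- 0.4 + 0.2 * dnorm(seq(-2, 2, length.out = 25))
  A <- rbind(ref, 2 + 3 * ref, ref)  # mean-spanned set keeps ref as mean shape
  s <- spectra_set(seq_len(25), A, toy_meta(3))
  out <- msc_fit_transform(s)
  # spectrum 2 was 2 + 3*reference-shape: corrected equals the set reference
  fit2 <- lm(A[2, ] ~ out$model$reference)
  expect_equal(out$corrected$absorbance[2, ],
               (A[2, ] - coef(fit2)[[1]]) / coef(fit2)[[2]], tolerance = 1e-10)

  # identical spectra: corrected equals input
  s_same <- spectra_set(seq_len(25), rbind(ref, ref), toy_meta(2))
  expect_equal(msc_fit_transform(s_same)$corrected$absorbance,
               s_same$absorbance, tolerance = 1e-12)
})

test_that("MSC refit of corrected spectra yields a=0, b=1", {
  s <- toy_spectra(8, 30)
  out <- msc_fit_transform(s)
  ref <- out$model$reference
  for (i in seq_len(8)) {
    fit <- lm(out$corrected$absorbance[i, ] ~ ref)
    expect_equal(coef(fit)[[1]], 0, tolerance = 1e-10)
    expect_equal(coef(fit)[[2]], 1, tolerance = 1e-10)
  }
})

test_that("MSC per-spectrum slope/offset solve the OLS normal equations", {
  s <- toy_spectra(5, 20)
  out <- msc_fit_transform(s)
  ref <- out$model$reference
  for (i in seq_len(5)) {
    fit <- lm(s$absorbance[i, ] ~ ref)
    expect_equal(out$model$a[i], coef(fit)[[1]], tolerance = 1e-10)
    expect_equal(out$model$b[i], coef(fit)[[2]], tolerance = 1e-10)
  }
})

test_that("msc_apply reproduces training output and enforces the grid", {
  s <- toy_spectra(6, 25)
  out <- msc_fit_transform(s)
  expect_equal(msc_apply(out$model, s)$absorbance,
               out$corrected$absorbance, tolerance = 1e-12)
  ref_only <- spectra_set(s$wavelengths, matrix(out$model$reference, 1),
                          toy_meta(1))
  expect_equal(msc_apply(out$model, ref_only)$absorbance[1, ],
               out$model$reference, tolerance = 1e-12)
  shifted <- spectra_set(s$wavelengths + 6.2, s$absorbance, s$meta)
  expect_error(msc_apply(out$model, shifted), "grid")
})

test_that("with a fixed reference, MSC undoes any per-spectrum affine distortion", {
  s <- toy_spectra(4, 25)
  model <- msc_fit_transform(s)$model
  # x = a + b * reference corrects back to the reference exactly
  aff <- spectra_set(s$wavelengths, matrix(2 + 3 * model$reference, 1),
                     toy_meta(1))
  expect_equal(msc_apply(model, aff)$absorbance[1, ], model$reference,
               tolerance = 1e-10)
  # distorting an arbitrary set row-wise leaves the corrected output unchanged
  a_i <- c(0.3, -0.1, 0, 0.7); b_i <- c(2, 0.5, 1.4, 3)
  distorted <- spectra_set(s$wavelengths,
                           s$absorbance * b_i + a_i, s$meta)
  expect_equal(msc_apply(model, distorted)$absorbance,
               msc_apply(model, s)$absorbance, tolerance = 1e-10)
})

test_that("MSC flags a degenerate (flat) spectrum by id", {
  s <- toy_spectra(3, 15)
  s$absorbance[2, ] <- 0.5  # constant: zero slope against any reference
  expect_error(msc_fit_transform(s), "s2")
})

test_that("difference spectra subtract the baseline day and drop its row", {
  wl <- seq_len(10)
  A <- rbind(rep(1, 10), rep(1, 10), rep(4, 10))
  meta <- tibble::tibble(day = c(3, 7, 17))
  s <- spectra_set(wl, A, meta)
  d <- difference_spectra(s, 3)
  expect_equal(n_spectra(d), 2)
  expect_equal(d$meta$day, c(7, 17))
  expect_equal(d$absorbance[1, ], rep(0, 10))  # day 7 == baseline
  expect_equal(d$absorbance[2, ], rep(3, 10))
  expect_error(difference_spectra(s, 99), "not present")
  expect_error(difference_spectra(
    spectra_set(wl, A, tibble::tibble(day = c(3, 3, 7))), 3), "one spectrum")
})
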