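#' Savitzky-Golay filter configuration
#'
#' @param window Odd window length in points (>= 5).
#' @param polyorder Polynomial order of the local fit (>= 2, < window).
#' @param deriv Derivative order (2 for second-derivative pretreatment).
#' @param scale `"per_index"` (derivative with respect to band index) or
#'   `"per_nm"` (divided by the grid step raised to `deriv`, i.e. a true
#'   derivative with respect to wavelength).
#' @return An `sg_config` list.
#' @export
sg_config <- function(window = 11L, polyorder = 2L, deriv = 2L,
                      scale = c("per_index", "per_nm")) {
  scale <- match.arg(scale)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window < 5L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 5")
  if (polyorder < 2L) stop("`polyorder` must be >= 2")
  if (polyorder >= window) stop("`polyorder` must be < `window`")
  if (deriv > polyorder) stop("`deriv` must be <= `polyorder`")
  structure(list(window = window, polyorder = polyorder, deriv = deriv,
                 scale = scale), class = "sg_config")
}

#' Savitzky-Golay derivative convolution kernel
#'
#' Solves the local polynomial least-squares normal equations for a centred
#' window; the kernel applied to the raw points yields the `deriv`-th
#' derivative of the fitted polynomial at the window centre (including the
#' `deriv`! factor, so a quadratic input with second-difference curvature c
#' yields exactly 2c).
#'
#' @param window Odd window length.
#' @param polyorder Polynomial order.
#' @param deriv Derivative order.
#' @return Numeric kernel of length `window`.
#' @keywords internal
sg_kernel <- function(window, polyorder, deriv) {
  h <- (window - 1L) %/% 2L
  x <- seq.int(-h, h)
  V <- outer(x, 0:polyorder, `^`)
  # row deriv+1 of (V'V)^{-1} V' gives the polynomial coefficient a_deriv
  coef_mat <- solve(crossprod(V), t(V))
  factorial(deriv) * coef_mat[deriv + 1L, ]
}

#' Savitzky-Golay derivative of a SpectraSet
#'
#' Convolves every spectrum with the SG derivative kernel. The
#' `(window - 1)/2` edge bands on each side, where the full window does not
#' fit, are dropped from the output grid (truncation, not padding: padded
#' derivatives are artifacts, and the downstream analyses use interior water
#' bands only).
#'
#' @param s A `SpectraSet`.
#' @param cfg An [sg_config()].
#' @return A `SpectraSet` on the interior grid.
#' @export
sg_derivative <- function(s, cfg = sg_config()) {
  assert_spectra_set(s)
  if (!inherits(cfg, "sg_config")) stop("`cfg` must be an sg_config")
  p <- n_bands(s)
  if (cfg$window >= p)
    stop("window (", cfg$window, ") must be smaller than the number of bands (",
         p, ")")
  k <- sg_kernel(cfg$window, cfg$polyorder, cfg$deriv)
  h <- (cfg$window - 1L) %/% 2L
  keep <- seq.int(h + 1L, p - h)
  # out[, j] = sum_m k[m] * A[, j - h - 1 + m]
  out <- matrix(0, n_spectra(s), length(keep))
  for (m in seq_along(k)) {
    cols <- keep - h - 1L + m
    out <- out + k[m] * s$absorbance[, cols, drop = FALSE]
  }
  if (cfg$scale == "per_nm") {
    step <- grid_step(s$wavelengths)
    out <- out / step^cfg$deriv
  }
  spectra_set(s$wavelengths[keep], out, s$meta)
}

#' Multiplicative scatter correction (fit and transform)
#'
#' Fits each spectrum against the set-mean reference by ordinary least
#' squares, `x ~ a + b * reference`, and returns the corrected spectra
#' `(x - a) / b` together with the fitted model. MSC removes per-spectrum
#' additive offsets and multiplicative scaling caused by scattering (leaf
#' thickness, surface properties).
#'
#' @param s A `SpectraSet` with at least 2 spectra.
#' @return A list with elements `corrected` (a `SpectraSet`) and `model`
#'   (an `msc_model` holding the reference spectrum and the per-spectrum
#'   offsets `a` and slopes `b`).
#' @export
msc_fit_transform <- function(s) {
  assert_spectra_set(s)
  if (n_spectra(s) < 2) stop("MSC needs at least 2 spectra")
  reference <- colMeans(s$absorbance)
  res <- msc_correct(s, reference)
  model <- structure(list(wavelengths = s$wavelengths, reference = reference,
                          a = res$a, b = res$b), class = "msc_model")
  list(corrected = res$corrected, model = model)
}

#' Apply a fitted MSC model to new spectra
#'
#' Uses the stored (training) reference; the band grid must match exactly.
#'
#' @param model An `msc_model` from [msc_fit_transform()].
#' @param s A `SpectraSet` on the same grid.
#' @return The corrected `SpectraSet`.
#' @export
msc_apply <- function(model, s) {
  if (!inherits(model, "msc_model")) stop("`model` must be an msc_model")
  assert_spectra_set(s)
  if (length(model$wavelengths) != n_bands(s) ||
      any(model$wavelengths != s$wavelengths))
    stop("band grid does not match the MSC training grid")
  msc_correct(s, model$reference)$corrected
}

msc_correct <- function(s, reference) {
  ref_c <- reference - mean(reference)
  denom <- sum(ref_c^2)
  if (denom < 1e-24) stop("degenerate (constant) MSC reference spectrum")
  b <- as.vector(s$absorbance %*% ref_c) / denom
  a <- rowMeans(s$absorbance) - b * mean(reference)
  if (any(abs(b) < 1e-12)) {
    bad <- which(abs(b) < 1e-12)[1]
    id <- if ("spectrum_id" %in% names(s$meta)) s$meta$spectrum_id[bad] else bad
    stop("degenerate spectrum in MSC (slope ~ 0): ", id)
  }
  corrected <- sweep(sweep(s$absorbance, 1, a, `-`), 1, b, `/`)
  list(corrected = spectra_set(s$wavelengths, corrected, s$meta), a = a, b = b)
}

#' Day-wise difference spectra against a baseline day
#'
#' Expects a group-averaged input with exactly one spectrum per day (e.g.
#' from [average_spectra()] with `by = "day"` on one line's stress spectra)
#' and subtracts the baseline day's spectrum from every other day's. The
#' baseline row is excluded from the output.
#'
#' @param s A `SpectraSet`, one spectrum per value of `meta$day`.
#' @param baseline_day The reference day (e.g. 3, the first measurement of
#'   the drought schedule).
#' @return A `SpectraSet` of differences with one row per non-baseline day.
#' @export
difference_spectra <- function(s, baseline_day) {
  assert_spectra_set(s)
  if (!"day" %in% names(s$meta)) stop("metadata must contain `day`")
  if (anyDuplicated(s$meta$day))
    stop("input must be group-averaged: one spectrum per day")
  i0 <- which(s$meta$day == baseline_day)
  if (length(i0) != 1) stop("baseline day ", baseline_day, " not present")
  keep <- setdiff(seq_len(n_spectra(s)), i0)
  diffs <- sweep(s$absorbance[keep, , drop = FALSE], 2,
                 s$absorbance[i0, ], `-`)
  meta <- s$meta[keep, , drop = FALSE]
  meta$baseline_day <- baseline_day
  spectra_set(s$wavelengths, diffs, meta)
}
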