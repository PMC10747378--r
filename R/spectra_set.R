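#' Construct a SpectraSet
#'
#' A `SpectraSet` is the common currency of the pipeline: a set of absorbance
#' spectra (log(1/R) convention) on a shared wavelength grid, together with
#' per-spectrum metadata describing the experimental design (line, plant,
#' leaf, replicate, treatment, measurement day).
#'
#' Wavelengths are stored strictly ascending; inputs supplied in descending
#' or shuffled order are re-sorted (and the absorbance columns permuted to
#' match) on construction.
#'
#' @param wavelengths Numeric vector of band centres in nm.
#' @param absorbance Numeric matrix, one row per spectrum, one column per
#'   band. No missing values are allowed.
#' @param meta Data frame of per-spectrum metadata with as many rows as
#'   `absorbance`. The canonical columns are `spectrum_id`, `line_label`,
#'   `plant_id`, `leaf_index` (2--4), `replicate` (1--3), `treatment`
#'   (`control`/`stress`/`recovery`), `day` and `stage_tag`; extra columns
#'   are carried along untouched.
#' @return An object of class `SpectraSet`.
#' @export
#' @examples
#' s <- spectra_set(c(1400, 1410, 1420), matrix(rnorm(6), 2, 3))
#' n_spectra(s)
spectra_set <- function(wavelengths, absorbance, meta = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (length(wavelengths) != ncol(absorbance))
    stop("`wavelengths` length (", length(wavelengths),
         ") != number of absorbance columns (", ncol(absorbance), ")")
  if (anyNA(wavelengths)) stop("`wavelengths` contains NA")
  if (anyDuplicated(wavelengths)) stop("duplicate wavelengths in grid")
  if (anyNA(absorbance))
    stop("absorbance matrix contains missing values; every spectrum must have all bands")
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]
  absorbance <- absorbance[, ord, drop = FALSE]
  if (is.null(meta)) {
    meta <- tibble::tibble(spectrum_id = paste0("s", seq_len(nrow(absorbance))))
  } else {
    meta <- tibble::as_tibble(meta)
  }
  if (nrow(meta) != nrow(absorbance))
    stop("`meta` has ", nrow(meta), " rows but absorbance has ",
         nrow(absorbance), " spectra")
  dimnames(absorbance) <- NULL
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 meta = meta),
            class = "SpectraSet")
}

#' @export
print.SpectraSet <- function(x, ...) {
  cat("<SpectraSet> ", n_spectra(x), " spectra x ", n_bands(x), " bands\n",
      sep = "")
  if (n_bands(x) > 0)
    cat("  grid: ", format(min(x$wavelengths)), "-",
        format(max(x$wavelengths)), " nm\n", sep = "")
  cat("  meta columns: ", paste(names(x$meta), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of spectra / bands in a SpectraSet
#' @param s A `SpectraSet`.
#' @return Integer count.
#' @export
n_spectra <- function(s) nrow(s$absorbance)

#' @rdname n_spectra
#' @export
n_bands <- function(s) ncol(s$absorbance)

assert_spectra_set <- function(s) {
  if (!inherits(s, "SpectraSet")) stop("expected a SpectraSet")
  invisible(s)
}

#' Restrict a SpectraSet to a wavelength window
#'
#' Keeps the bands with `lo <= lambda <= hi` (inclusive). Used e.g. to
#' restrict PLS calibration to the 1300--1600 nm first-overtone region.
#'
#' @param s A `SpectraSet`.
#' @param lo,hi Window bounds in nm, `lo < hi`.
#' @return A `SpectraSet` on the restricted grid; metadata unchanged.
#' @export
select_wavelength_range <- function(s, lo, hi) {
  assert_spectra_set(s)
  if (!(lo < hi)) stop("`lo` must be < `hi`")
  keep <- s$wavelengths >= lo & s$wavelengths <= hi
  if (!any(keep))
    stop("no band falls in [", lo, ", ", hi, "] nm (grid spans ",
         min(s$wavelengths), "-", max(s$wavelengths), " nm)")
  spectra_set(s$wavelengths[keep], s$absorbance[, keep, drop = FALSE], s$meta)
}

#' Subset spectra by a metadata predicate
#'
#' @param s A `SpectraSet`.
#' @param predicate An expression evaluated in the metadata (tidy
#'   evaluation), e.g. `treatment == "stress"`.
#' @return A `SpectraSet` with the matching rows, order preserved.
#' @export
#' @examples
#' \dontrun{subset_spectra(s, treatment == "stress" & leaf_index == 3)}
subset_spectra <- function(s, predicate) {
  assert_spectra_set(s)
  expr <- rlang::enquo(predicate)
  used <- all.vars(rlang::get_expr(expr))
  missing_fields <- setdiff(intersect(used, used), c(names(s$meta)))
  # only flag symbols that are not resolvable in the calling environment
  missing_fields <- missing_fields[!vapply(
    missing_fields, function(v) exists(v, envir = rlang::quo_get_env(expr)),
    logical(1))]
  if (length(missing_fields))
    stop("unknown metadata field(s): ", paste(missing_fields, collapse = ", "))
  keep <- rlang::eval_tidy(expr, data = s$meta)
  if (!is.logical(keep) || length(keep) != n_spectra(s))
    stop("predicate must evaluate to one logical per spectrum")
  keep[is.na(keep)] <- FALSE
  spectra_set(s$wavelengths, s$absorbance[keep, , drop = FALSE],
              s$meta[keep, , drop = FALSE])
}

#' Group-wise mean spectra
#'
#' Averages spectra within groups defined by metadata fields, producing one
#' spectrum per group (the arithmetic mean over member spectra).
#'
#' @param s A `SpectraSet`.
#' @param by Character vector of metadata field names, e.g.
#'   `c("line_label", "treatment", "day")`.
#' @return A `SpectraSet` with one row per group; the metadata carries the
#'   grouping labels plus an `n_members` count.
#' @export
average_spectra <- function(s, by) {
  assert_spectra_set(s)
  if (n_spectra(s) == 0) stop("cannot average an empty SpectraSet")
  if (!length(by)) stop("`by` must name at least one metadata field")
  bad <- setdiff(by, names(s$meta))
  if (length(bad)) stop("unknown metadata field(s): ", paste(bad, collapse = ", "))
  key <- s$meta[by]
  gid <- do.call(paste, c(as.list(key), sep = "\r"))
  levels_in_order <- unique(gid)
  gfac <- factor(gid, levels = levels_in_order)
  means <- rowsum(s$absorbance, gfac) / as.vector(table(gfac))
  meta_out <- key[!duplicated(gid), , drop = FALSE]
  meta_out$n_members <- as.vector(table(gfac))
  spectra_set(s$wavelengths, means, meta_out)
}

#' Index of the grid band nearest to a target wavelength
#'
#' Ties (a target exactly midway between two bands) break toward the lower
#' wavelength, deterministically.
#'
#' @param wavelengths Ascending numeric grid in nm.
#' @param target Target wavelength in nm.
#' @return Integer index into `wavelengths`.
#' @export
nearest_band_index <- function(wavelengths, target) {
  if (!length(wavelengths)) stop("empty wavelength grid")
  d <- abs(wavelengths - target)
  # tolerance makes the tie-to-lower rule robust to floating-point noise
  which(d <= min(d) + 1e-9 * (abs(target) + 1))[1]
}

grid_step <- function(wavelengths, tol = 0.05) {
  d <- diff(wavelengths)
  if (length(d) == 0) return(NA_real_)
  step <- stats::median(d)
  if (any(abs(d - step) > tol * step))
    warning("wavelength grid spacing varies by more than ", tol * 100,
            "% of the median step")
  step
}
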