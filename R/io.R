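META_COLUMNS <- c("spectrum_id", "line_label", "plant_id", "leaf_index",
                  "replicate", "treatment", "day", "stage_tag")

#' Read a SpectraSet from CSV
#'
#' Two dialects are supported. `wide_csv` (the canonical exchange format):
#' metadata columns first, then one numeric column per band, named by the
#' band-centre wavelength in nm. `long_csv`: one row per
#' (spectrum, wavelength) with columns `wavelength` and `absorbance` plus the
#' metadata columns repeated per row.
#'
#' Wavelength columns in any order are normalised to an ascending grid on
#' load. In the long dialect every spectrum must carry every band.
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @return A `SpectraSet`.
#' @export
load_spectra <- function(path, dialect = c("wide_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "wide_csv") {
    is_wl <- suppressWarnings(!is.na(as.numeric(names(df))))
    meta_cols <- names(df)[!is_wl]
    missing <- setdiff(META_COLUMNS, meta_cols)
    if (length(missing))
      stop("missing metadata column(s): ", paste(missing, collapse = ", "))
    wl <- as.numeric(names(df)[is_wl])
    if (!length(wl)) stop("no wavelength columns found in ", path)
    A <- as.matrix(df[is_wl])
    if (anyNA(A)) {
      bad <- which(rowSums(is.na(A)) > 0)[1]
      stop("missing absorbance value(s), first at data row ", bad)
    }
    spectra_set(wl, A, df[meta_cols])
  } else {
    needed <- c(META_COLUMNS, "wavelength", "absorbance")
    missing <- setdiff(needed, names(df))
    if (length(missing))
      stop("missing column(s): ", paste(missing, collapse = ", "))
    wl <- sort(unique(df$wavelength))
    ids <- unique(df$spectrum_id)
    counts <- table(df$spectrum_id)
    if (any(counts != length(wl))) {
      bad <- names(counts)[counts != length(wl)][1]
      stop("spectrum ", bad, " does not carry every band (",
           counts[bad], " of ", length(wl), ")")
    }
    A <- matrix(NA_real_, length(ids), length(wl))
    row_i <- match(df$spectrum_id, ids)
    col_i <- match(df$wavelength, wl)
    A[cbind(row_i, col_i)] <- df$absorbance
    if (anyNA(A)) stop("duplicate or missing (spectrum, wavelength) pairs")
    meta <- df[!duplicated(df$spectrum_id), META_COLUMNS]
    spectra_set(wl, A, meta)
  }
}

#' Write a SpectraSet to CSV
#'
#' The inverse of [load_spectra()]: metadata and wavelengths round-trip
#' exactly, absorbance to better than 12 significant digits.
#'
#' @param s A `SpectraSet`.
#' @param path Output path.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, dialect = c("wide_csv", "long_csv")) {
  assert_spectra_set(s)
  dialect <- match.arg(dialect)
  meta <- s$meta
  for (mc in setdiff(META_COLUMNS, names(meta))) meta[[mc]] <- NA
  meta <- meta[c(META_COLUMNS, setdiff(names(meta), META_COLUMNS))]
  if (dialect == "wide_csv") {
    A <- s$absorbance
    colnames(A) <- format_wavelength(s$wavelengths)
    out <- dplyr::bind_cols(meta, tibble::as_tibble(A))
  } else {
    nb <- n_bands(s)
    idx <- rep(seq_len(n_spectra(s)), each = nb)
    out <- meta[idx, , drop = FALSE]
    out$wavelength <- rep(s$wavelengths, times = n_spectra(s))
    out$absorbance <- as.vector(t(s$absorbance))
  }
  ok <- tryCatch({
    readr::write_csv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

format_wavelength <- function(wl) {
  # >= 3 decimals so printed WAMAC positions survive the round trip
  formatC(wl, format = "f", digits = 6, drop0trailing = FALSE)
}
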