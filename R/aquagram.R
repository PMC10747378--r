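#' The 19 water matrix coordinates (WAMACs)
#'
#' Returns the 19 first-overtone water matrix coordinates used as aquagram
#' axes: codes C1--C19 with band-centre wavelengths (nm) and chemical
#' annotations (proton/ion hydration and trapped water below 1391 nm, free
#' water at 1409 nm, water with 1--4 hydrogen bonds through the 1440--1490 nm
#' region, and strongly bound/structural water interacting with protein and
#' cellulose above 1460 nm).
#'
#' @return A tibble with columns `code`, `wavelength`, `annotation`.
#' @export
default_wamacs <- function() {
  tibble::tibble(
    code = paste0("C", 1:19),
    wavelength = c(1347.899, 1360.288, 1372.677, 1385.065, 1391.26,
                   1409.843, 1416.037, 1422.231, 1440.814, 1447.009,
                   1453.203, 1465.592, 1471.786, 1490.369, 1502.758,
                   1515.147, 1521.341, 1533.73, 1570.896),
    annotation = c(
      "water shell / hydration water",
      "proton hydration (H3O+)",
      "ion hydration, water shell",
      "trapped water",
      "water confined / trapped",
      "free water",
      "free water / water vapour-like",
      "water hydration band",
      "water with 1 hydrogen bond",
      "water hydration / desiccation band",
      "water with 1-2 hydrogen bonds",
      "water with 2 hydrogen bonds; protein-water",
      "water with 3 hydrogen bonds",
      "water with 4 hydrogen bonds",
      "strongly bound water; water-cellulose",
      "strongly bound water",
      "water-cellulose interaction",
      "structural water, water-cellulose",
      "strongly bound / crystalline-like water"
    )
  )
}

validate_wamacs <- function(w) {
  stopifnot(is.data.frame(w),
            all(c("code", "wavelength") %in% names(w)))
  if (nrow(w) != 19) stop("a WAMAC table must have exactly 19 entries")
  if (is.unsorted(w$wavelength, strictly = TRUE))
    stop("WAMAC wavelengths must be strictly increasing")
  if (any(w$wavelength < 1300 | w$wavelength > 1600))
    stop("WAMAC wavelengths must lie within 1300-1600 nm")
  invisible(w)
}

#' Compute an aquagram
#'
#' For each WAMAC wavelength lambda the absorbance is standardised across
#' the whole population of supplied spectra,
#' `Aq = (A - mu) / sigma`,
#' where `mu` and `sigma` are the mean and (sample, n-1) standard deviation
#' of the absorbance of all spectra at that wavelength. The shared
#' normalisation population (all treatments together) is what makes group
#' aquagrams comparable. Group aquagrams are means of the per-spectrum `Aq`
#' within each group.
#'
#' Spectra are expected to be MSC-corrected first (see
#' [msc_fit_transform()]); this function does not itself apply any
#' pretreatment.
#'
#' @param s A `SpectraSet` (>= 2 spectra).
#' @param wamacs A WAMAC table, by default [default_wamacs()]. Each WAMAC is
#'   mapped to the nearest grid band; a warning is issued if the nearest
#'   band is further than half a grid step away.
#' @param by Character vector of metadata fields defining the groups whose
#'   mean aquagrams are reported (default `"treatment"`).
#' @return An `aquagram_result` with elements `wamacs`, `per_spectrum_aq`
#'   (n_spectra x 19), `group_aq` (tibble: group labels, `n_members`, one
#'   column per WAMAC code), `mu`, `sigma`, `band_index`, `meta`.
#' @export
compute_aquagram <- function(s, wamacs = default_wamacs(), by = "treatment") {
  assert_spectra_set(s)
  validate_wamacs(wamacs)
  if (n_spectra(s) < 2) stop("aquagram normalisation needs at least 2 spectra")
  bad <- setdiff(by, names(s$meta))
  if (length(bad)) stop("unknown metadata field(s): ", paste(bad, collapse = ", "))
  idx <- vapply(wamacs$wavelength, nearest_band_index,
                integer(1), wavelengths = s$wavelengths)
  step <- abs(grid_step(s$wavelengths))
  off <- abs(s$wavelengths[idx] - wamacs$wavelength)
  if (any(off > step / 2))
    warning("WAMAC(s) ", paste(wamacs$code[off > step / 2], collapse = ", "),
            " are further than half a grid step from the nearest band; ",
            "nearest band used")
  A <- s$absorbance[, idx, drop = FALSE]
  mu <- colMeans(A)
  sigma <- apply(A, 2, stats::sd)
  if (any(sigma < 1e-12))
    stop("degenerate variance at WAMAC(s) ",
         paste(wamacs$code[sigma < 1e-12], collapse = ", "))
  aq <- sweep(sweep(A, 2, mu, `-`), 2, sigma, `/`)
  colnames(aq) <- wamacs$code
  key <- s$meta[by]
  gid <- do.call(paste, c(as.list(key), sep = "\r"))
  gfac <- factor(gid, levels = unique(gid))
  gmeans <- rowsum(aq, gfac) / as.vector(table(gfac))
  group_aq <- dplyr::bind_cols(
    key[!duplicated(gid), , drop = FALSE],
    tibble::tibble(n_members = as.vector(table(gfac))),
    tibble::as_tibble(gmeans))
  structure(list(wamacs = wamacs, per_spectrum_aq = aq, group_aq = group_aq,
                 mu = mu, sigma = sigma, band_index = idx,
                 group_by = by, meta = s$meta),
            class = "aquagram_result")
}

#' @export
print.aquagram_result <- function(x, ...) {
  cat("<aquagram_result> ", nrow(x$per_spectrum_aq), " spectra, ",
      nrow(x$group_aq), " group(s) over ", nrow(x$wamacs), " WAMACs\n", sep = "")
  invisible(x)
}

#' Export an aquagram to CSV and a radar chart
#'
#' Writes the group aquagram as a CSV (one row per group, one column per
#' WAMAC, named `code_wavelength`) and, optionally, a radar chart with one
#' closed polygon per group, axes ordered C1 to C19.
#'
#' @param r An `aquagram_result`.
#' @param path Output CSV path; the figure (if any) is written next to it
#'   with the same stem.
#' @param plot Whether to attempt the radar chart (requires a working PNG
#'   device).
#' @return Character vector of files written, invisibly.
#' @export
export_aquagram <- function(r, path, plot = TRUE) {
  if (!inherits(r, "aquagram_result")) stop("expected an aquagram_result")
  out <- r$group_aq
  codes <- r$wamacs$code
  value_names <- paste0(codes, "_", r$wamacs$wavelength)
  names(out)[match(codes, names(out))] <- value_names
  ok <- tryCatch({
    readr::write_csv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  written <- path
  if (plot) {
    fig <- sub("\\.csv$", ".png", path)
    if (identical(fig, path)) fig <- paste0(path, ".png")
    gp <- plot_aquagram(r)
    dev_ok <- tryCatch({
      grDevices::png(fig, width = 1400, height = 1100, res = 160)
      print(gp)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      warning("radar chart skipped (no PNG device): ", conditionMessage(e))
      FALSE
    })
    if (isTRUE(dev_ok)) written <- c(written, fig)
  }
  invisible(written)
}

#' Radar-chart (aquagram) plot
#'
#' @param r An `aquagram_result`.
#' @return A ggplot object: one closed polygon per group on polar axes
#'   C1..C19.
#' @export
plot_aquagram <- function(r) {
  codes <- r$wamacs$code
  df <- r$group_aq
  group_lab <- do.call(paste, c(as.list(df[r$group_by]), sep = " / "))
  long <- tibble::tibble(
    group = rep(group_lab, times = length(codes)),
    code = factor(rep(codes, each = nrow(df)), levels = codes),
    aq = unlist(df[codes], use.names = FALSE))
  # close the polygons by repeating C1 after C19
  first <- long[long$code == codes[1], ]
  first$position <- length(codes) + 1
  long$position <- as.integer(long$code)
  long <- rbind(long, first)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$aq,
                                     group = .data$group,
                                     colour = .data$group)) +
    ggplot2::geom_path() +
    ggplot2::coord_polar() +
    ggplot2::scale_x_continuous(breaks = seq_along(codes), labels = codes,
                                limits = c(1, length(codes) + 1)) +
    ggplot2::labs(x = NULL, y = "Aq (z-score)", colour = NULL,
                  title = "Aquagram") +
    ggplot2::theme_minimal()
}
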