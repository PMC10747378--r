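#' Pipeline configuration
#'
#' Bundles all settings of the end-to-end analysis: the input (a wide-CSV
#' spectra file or a synthetic-generator configuration), pretreatment
#' settings, the PLS wavelength window, aquagram grouping, CV settings and
#' the output directory.
#'
#' @param input Path to a wide-CSV spectra file, or `NULL` to generate
#'   synthetic data from `generator`.
#' @param generator A [generator_config()] (used when `input` is `NULL`).
#' @param sg An [sg_config()] for the derivative/PLS path.
#' @param window Wavelength window (nm) for the PLS calibration.
#' @param aquagram_by Metadata fields defining aquagram groups.
#' @param baseline_day Baseline day for difference spectra.
#' @param max_factors PLS factor search bound.
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed forwarded to the generator.
#' @param figures Whether to write figure files alongside the CSV twins.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, generator = generator_config(),
                            sg = sg_config(), window = c(1300, 1600),
                            aquagram_by = c("line_label", "leaf_index",
                                            "treatment"),
                            baseline_day = 3, max_factors = 10L,
                            out_dir = "aqualeaf_out", seed = 1L,
                            figures = TRUE) {
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  structure(list(input = input, generator = generator, sg = sg,
                 window = window, aquagram_by = aquagram_by,
                 baseline_day = baseline_day,
                 max_factors = as.integer(max_factors),
                 out_dir = out_dir, seed = as.integer(seed),
                 figures = isTRUE(figures)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg A `pipeline_config`.
#' @return Character vector of human-readable issues; empty iff runnable.
#' @export
validate_config <- function(cfg) {
  issues <- character(0)
  chk <- function(ok, msg) if (!ok) issues <<- c(issues, msg)
  if (!is.null(cfg$input)) {
    chk(file.exists(cfg$input), paste("input file not found:", cfg$input))
    grid_lo <- NA; grid_hi <- NA
  } else {
    gi <- validate_generator_config(cfg$generator)
    issues <- c(issues, gi)
    grid_lo <- min(cfg$generator$grid); grid_hi <- max(cfg$generator$grid)
  }
  chk(length(cfg$window) == 2 && cfg$window[1] < cfg$window[2],
      paste("window must be (lo, hi) with lo < hi; got",
            paste(cfg$window, collapse = ", ")))
  if (!is.na(grid_lo) && length(cfg$window) == 2)
    chk(cfg$window[1] < grid_hi && cfg$window[2] > grid_lo,
        paste0("window [", cfg$window[1], ", ", cfg$window[2],
               "] lies outside the wavelength grid"))
  chk(cfg$max_factors >= 1, "max_factors must be >= 1")
  issues
}

#' Run the full aquaphotomics pipeline
#'
#' Executes load/generate, group-mean second-derivative and difference
#' spectra, MSC + aquagrams per group, per-WAMAC significance tables, and a
#' PLS drought-day calibration per line with grouped cross-validation,
#' regression vector and correlation spectrum. Every artifact is written to
#' `cfg$out_dir` as CSV (figures get a CSV twin) and listed in a JSON
#' manifest together with the resolved configuration; the whole bundle is
#' deterministic for a fixed seed.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  issues <- validate_config(cfg)
  if (length(issues))
    stop("invalid pipeline config:\n  - ", paste(issues, collapse = "\n  - "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_stage <- function(stage, msg) message("[", stage, "] ", msg)
  emit <- function(name) { files <<- c(files, name); file.path(cfg$out_dir, name) }
  stage <- "load"
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("aqualeaf")),
                   settings = list(
                     window = cfg$window, sg = unclass(cfg$sg),
                     aquagram_by = cfg$aquagram_by,
                     baseline_day = cfg$baseline_day,
                     max_factors = cfg$max_factors,
                     input = if (is.null(cfg$input)) "synthetic" else cfg$input))
  result <- tryCatch({
    ## -- load or generate -------------------------------------------------
    if (is.null(cfg$input)) {
      gen <- generate_experiment(cfg$generator)
      s <- gen$spectra
      readr::write_csv(gen$truth, emit("ground_truth.csv"), progress = FALSE)
      write_spectra(s, emit("spectra.csv"), "wide_csv")
    } else {
      s <- load_spectra(cfg$input, "wide_csv")
    }
    log_stage(stage, paste(n_spectra(s), "spectra x", n_bands(s), "bands"))

    ## -- derivative spectra (per line x treatment x day means) -----------
    stage <- "derivative"
    d2 <- sg_derivative(s, cfg$sg)
    d2_means <- average_spectra(d2, c("line_label", "treatment", "day"))
    write_spectra(d2_means, emit("second_derivative_group_means.csv"),
                  "wide_csv")

    ## -- difference spectra per line (stress arm) ------------------------
    stage <- "difference"
    for (ln in unique(s$meta$line_label)) {
      st <- subset_spectra(d2, treatment == "stress" & line_label == ln)
      if (n_spectra(st) == 0) next
      dm <- average_spectra(st, "day")
      ds <- difference_spectra(dm, cfg$baseline_day)
      write_spectra(ds, emit(paste0("difference_spectra_", ln, ".csv")),
                    "wide_csv")
    }

    ## -- MSC + aquagrams --------------------------------------------------
    stage <- "aquagram"
    msc <- msc_fit_transform(s)
    aq <- compute_aquagram(msc$corrected, by = cfg$aquagram_by)
    export_aquagram(aq, emit("aquagram_groups.csv"), plot = FALSE)
    if (cfg$figures) {
      fig <- file.path(cfg$out_dir, "aquagram_groups.png")
      ok <- tryCatch({
        grDevices::png(fig, width = 1400, height = 1100, res = 160)
        print(plot_aquagram(aq))
        grDevices::dev.off(); TRUE
      }, error = function(e) { try(grDevices::dev.off(), silent = TRUE); FALSE })
      if (ok) files <- c(files, "aquagram_groups.png")
    }

    ## -- significance tables ----------------------------------------------
    stage <- "significance"
    aq_t <- compute_aquagram(msc$corrected, by = "treatment")
    sig <- wamac_significance(aq_t, "treatment")
    readr::write_csv(sig, emit("wamac_significance.csv"), progress = FALSE)

    ## -- PLS per line ------------------------------------------------------
    stage <- "pls"
    d2w <- select_wavelength_range(d2, cfg$window[1], cfg$window[2])
    pls_reports <- list()
    for (ln in unique(s$meta$line_label)) {
      st <- subset_spectra(d2w, treatment == "stress" & line_label == ln)
      if (n_spectra(st) < 6) next
      gid <- paste(st$meta$plant_id, st$meta$leaf_index, st$meta$day)
      cv <- grouped_cv(st$absorbance, st$meta$day, gid,
                       max_factors = cfg$max_factors,
                       wavelengths = st$wavelengths)
      log_stage(stage, sprintf("%s: factors=%d SECV=%.3f R2cv=%.3f",
                               ln, cv$n_factors, cv$secv, cv$r2cv))
      rv <- tibble::tibble(wavelength = st$wavelengths,
                           coefficient = cv$model$regression_vector)
      readr::write_csv(rv, emit(paste0("regression_vector_", ln, ".csv")),
                       progress = FALSE)
      cs <- tibble::tibble(
        wavelength = st$wavelengths,
        r = correlation_spectrum(st$absorbance, st$meta$day))
      readr::write_csv(cs, emit(paste0("correlation_spectrum_", ln, ".csv")),
                       progress = FALSE)
      top <- important_bands(cv$model, 5L)
      pls_reports[[ln]] <- list(
        line = ln, n_spectra = n_spectra(st), n_bands = n_bands(st),
        n_factors = cv$n_factors, secv = cv$secv, sec = cv$sec,
        r2cv = cv$r2cv, r2cal = cv$r2cal, r2cv_press = cv$r2cv_press,
        secv_curve = as.vector(cv$secv_curve),
        top_bands = top$wavelength)
    }
    pls_path <- emit("pls_report.json")
    jsonlite::write_json(pls_reports, pls_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(spectra = s, aquagram = aq, significance = sig, pls = pls_reports)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$files <- files
  manifest$n_files <- length(files)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(results = result)))
}
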