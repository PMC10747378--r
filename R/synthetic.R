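#' Default wavelength grid of the synthetic instrument
#'
#' A uniform 6.1945 nm pixel pitch anchored at the 1347.899 nm WAMAC,
#' spanning 908-1670 nm (124 bands); the 19 grid points nearest the WAMAC
#' wavelengths are snapped to their exact printed values so that the
#' WAMAC-to-band mapping is exact on synthetic data.
#'
#' @return Ascending numeric grid in nm.
#' @export
default_grid <- function() {
  pitch <- 6.1945
  k <- seq.int(-71L, 52L)
  grid <- 1347.899 + pitch * k
  for (wl in default_wamacs()$wavelength) {
    grid[nearest_band_index(grid, wl)] <- wl
  }
  grid
}

#' Synthetic drought-experiment generator configuration
#'
#' Encodes the study design the analysis assumes: two maize inbred lines
#' (one drought-tolerant with a late stress onset, one sensitive with an
#' early onset), 10 stressed + 10 control plants per line, leaves 2-4 each
#' measured at 3 positions, a drought schedule of days 3, 7, 10, 12, 14, 17
#' followed by 2 rewatering measurements, and a water-band forward model:
#' free / weakly hydrogen-bonded bands (1300-1430 nm region, dominated by
#' the 1409 nm free-water band) lose amplitude linearly after the line's
#' onset day while strongly hydrogen-bonded / structural-water bands
#' (1440-1535 nm) gain proportionally; recovery spectra stay at the day-17
#' state with an extra gain of the bound-water bands above 1500 nm
#' (desiccated leaves retain mainly cellulose-bound water).
#'
#' @param grid Wavelength grid (default [default_grid()]).
#' @param lines Named vector of stress onset days; names are the line
#'   labels. Default: sensitive onset day 3, tolerant onset day 7 (the
#'   tolerant genotype shows no spectral change until day 7).
#' @param n_plants_per_arm Plants per line per arm (stress / control).
#' @param leaves,replicates Leaf indices measured and replicate positions
#'   per leaf.
#' @param stress_days,recovery_days Measurement schedule (recovery days are
#'   days after rewatering).
#' @param bands Tibble of the forward model: `center`, `width` (nm),
#'   `base` amplitude (absorbance), `slope` (absorbance change per day of
#'   drought past onset; negative = band declines under stress).
#' @param recovery_extra Additional amplitude added to bands above 1500 nm
#'   in recovery spectra.
#' @param scatter_slope_sd,scatter_offset_sd SDs of the per-spectrum
#'   multiplicative slope (around 1) and additive offset (around 0).
#' @param noise_sd SD of iid band noise (absorbance units).
#' @param leaf_effect_sd SD of the per-(plant, leaf) multiplicative random
#'   effect on band amplitudes.
#' @param progression_jitter_sd Relative SD of the per-(plant, occasion)
#'   drought-progression jitter: the effective days past onset of a plant
#'   on a given occasion are `max(0, day - onset) * (1 + jitter)`, shared
#'   by all of that plant's leaves and replicates. This models the
#'   biological reality that individual plants dry at different rates, and
#'   it is the main irreducible error of the drought-day calibration.
#' @param day_slope_scale Global multiplier on all `slope` values; 0 turns
#'   the drought signal off entirely (negative control).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(grid = default_grid(),
                             lines = c(sensitive = 3, tolerant = 7),
                             n_plants_per_arm = 10L,
                             leaves = 2:4,
                             replicates = 1:3,
                             stress_days = c(3, 7, 10, 12, 14, 17),
                             recovery_days = c(3, 4),
                             bands = default_bands(),
                             recovery_extra = 0.03,
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.01,
                             noise_sd = 0.003,
                             leaf_effect_sd = 0.02,
                             progression_jitter_sd = 0.12,
                             day_slope_scale = 1,
                             seed = 1L) {
  cfg <- list(grid = grid, lines = lines,
              n_plants_per_arm = as.integer(n_plants_per_arm),
              leaves = as.integer(leaves), replicates = as.integer(replicates),
              stress_days = stress_days, recovery_days = recovery_days,
              bands = tibble::as_tibble(bands),
              recovery_extra = recovery_extra,
              scatter_slope_sd = scatter_slope_sd,
              scatter_offset_sd = scatter_offset_sd,
              noise_sd = noise_sd, leaf_effect_sd = leaf_effect_sd,
              progression_jitter_sd = progression_jitter_sd,
              day_slope_scale = day_slope_scale,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  issues <- validate_generator_config(cfg)
  if (length(issues))
    stop("invalid generator config:\n  - ", paste(issues, collapse = "\n  - "))
  cfg
}

#' @rdname generator_config
#' @param cfg A `generator_config`.
#' @return For `validate_generator_config()`, a character vector of issues
#'   (empty when the configuration is valid).
#' @export
validate_generator_config <- function(cfg) {
  issues <- character(0)
  chk <- function(ok, msg) if (!ok) issues <<- c(issues, msg)
  chk(length(cfg$grid) >= 5 && !is.unsorted(cfg$grid, strictly = TRUE),
      "grid must be strictly ascending with >= 5 bands")
  chk(length(cfg$lines) >= 1 && !is.null(names(cfg$lines)),
      "lines must be a named vector of onset days")
  chk(all(cfg$lines %in% cfg$stress_days),
      "every onset day must lie within the stress-day schedule")
  chk(cfg$n_plants_per_arm >= 1, "n_plants_per_arm must be >= 1")
  chk(all(c("center", "width", "base", "slope") %in% names(cfg$bands)),
      "bands needs columns center, width, base, slope")
  chk(all(cfg$bands$base >= 0), "band base amplitudes must be >= 0")
  chk(all(cfg$bands$width > 0), "band widths must be > 0")
  for (f in c("scatter_slope_sd", "scatter_offset_sd", "noise_sd",
              "leaf_effect_sd", "progression_jitter_sd"))
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, paste(f, "must be >= 0"))
  chk(all(cfg$bands$center > min(cfg$grid) & cfg$bands$center < max(cfg$grid)),
      "band centers must lie within the grid span")
  issues
}

#' Default water-band forward model
#'
#' Gaussian bands at the two short-wave water bands (930, 1155 nm) and the
#' 19 WAMACs. Negative slopes (free / weakly bound water, <= 1422 nm)
#' shrink with days of drought; positive slopes (strongly bound /
#' structural water, >= 1441 nm) grow. The free-water band at 1409.843 nm
#' carries the largest day effect (0.010 absorbance per day), making it the
#' most informative single band for drought-day calibration.
#'
#' @return Tibble with `center`, `width`, `base`, `slope`.
#' @export
default_bands <- function() {
  w <- default_wamacs()$wavelength
  tibble::tibble(
    center = c(930, 1155, w),
    width = c(20, 25, 14, 14, 14, 14, 13, 13, 12, 12,
              13, 13, 14, 14, 14, 15, 15, 16, 16, 18, 20),
    base = c(0.15, 0.35, 0.30, 0.32, 0.34, 0.36, 0.38, 0.50, 0.46, 0.44,
             0.42, 0.42, 0.42, 0.40, 0.40, 0.38, 0.34, 0.30, 0.28, 0.26,
             0.20),
    slope = c(-0.002, -0.004,
              -0.004, -0.006, -0.007, -0.008, -0.008, -0.010, -0.004, -0.003,
              0.005, 0.005, 0.005, 0.005, 0.005, 0.005, 0.005, 0.005, 0.004,
              0.004, 0.001))
}

#' Noiseless band amplitudes for a design cell
#'
#' Control plants keep the baseline amplitudes on every day. Stressed
#' plants change linearly after their line's onset day:
#' `amplitude = base + slope * max(0, day - onset)`. Recovery plants hold
#' the day-17 state (leaves do not rehydrate within the rewatering window),
#' with `recovery_extra` added to the strongly-bound-water bands above
#' 1500 nm.
#'
#' @param day Measurement day (for recovery: ignored for the trajectory,
#'   which is pinned at the last stress day).
#' @param treatment `"control"`, `"stress"` or `"recovery"`.
#' @param line Line label (must be a name of `cfg$lines`).
#' @param cfg A `generator_config`.
#' @return Numeric amplitude vector, one per band of `cfg$bands`.
#' @export
band_amplitudes <- function(day, treatment, line, cfg) {
  if (!line %in% names(cfg$lines)) stop("unknown line: ", line)
  amplitudes_at(effective_days(day, treatment, line, cfg), treatment, cfg)
}

# noiseless days past onset for a design cell
effective_days <- function(day, treatment, line, cfg) {
  onset <- cfg$lines[[line]]
  if (treatment == "control") 0
  else if (treatment == "stress") max(0, day - onset)
  else if (treatment == "recovery") max(0, max(cfg$stress_days) - onset)
  else stop("unknown treatment: ", treatment)
}

# linear-after-onset amplitude trajectory, clamped at zero
amplitudes_at <- function(eff_days, treatment, cfg) {
  amp <- pmax(0, cfg$bands$base +
                cfg$bands$slope * cfg$day_slope_scale * eff_days)
  if (treatment == "recovery")
    amp <- amp + ifelse(cfg$bands$center > 1500, cfg$recovery_extra, 0)
  amp
}

#' Render a spectrum from band amplitudes
#'
#' Deterministic instrument forward model: a sum of Gaussian bands,
#' `sum_k amp_k exp(-(lambda - center_k)^2 / (2 width_k^2))`, on top of a
#' smooth, gently sloping baseline shared by all spectra.
#'
#' @param amplitudes Amplitude vector matching `cfg$bands`.
#' @param cfg A `generator_config`.
#' @return Numeric absorbance spectrum on `cfg$grid`.
#' @export
render_spectrum <- function(amplitudes, cfg) {
  lam <- cfg$grid
  out <- synth_baseline(lam)
  for (k in seq_along(amplitudes)) {
    if (amplitudes[k] == 0) next
    out <- out + amplitudes[k] *
      exp(-(lam - cfg$bands$center[k])^2 / (2 * cfg$bands$width[k]^2))
  }
  out
}

synth_baseline <- function(lam) {
  0.20 + 1.5e-4 * (lam - 908)
}

#' Generate a full synthetic drought experiment
#'
#' Builds the crossed design (line x plant x leaf x measurement occasion x
#' replicate): per line, `n_plants_per_arm` stressed plants measured on the
#' stress schedule (treatment `stress`) and on the rewatering days
#' (treatment `recovery`), plus `n_plants_per_arm` control plants measured
#' on the same occasions. Each spectrum is
#' `b * render(amplitudes * (1 + u)) + a + noise`
#' with per-spectrum scatter slope `b ~ N(1, scatter_slope_sd)` and offset
#' `a ~ N(0, scatter_offset_sd)`, a per-(plant, leaf) multiplicative random
#' effect `u ~ N(0, leaf_effect_sd)` shared by all of that leaf's spectra,
#' and iid band noise.
#'
#' @param cfg A `generator_config`.
#' @return A list with `spectra` (a `SpectraSet`) and `truth` (a tibble of
#'   per-spectrum noiseless amplitudes at the 1409 nm free-water band,
#'   scatter parameters, leaf effects and the effective day signal).
#' @export
generate_experiment <- function(cfg = generator_config()) {
  if (!inherits(cfg, "generator_config"))
    stop("`cfg` must be a generator_config")
  issues <- validate_generator_config(cfg)
  if (length(issues))
    stop("invalid generator config:\n  - ", paste(issues, collapse = "\n  - "))
  set.seed(cfg$seed)
  occasions <- rbind(
    data.frame(stage_tag = "drought", day = cfg$stress_days),
    data.frame(stage_tag = "rewatering", day = cfg$recovery_days))
  design <- expand.grid(
    replicate = cfg$replicates, occ = seq_len(nrow(occasions)),
    leaf_index = cfg$leaves, plant = seq_len(2L * cfg$n_plants_per_arm),
    line_label = names(cfg$lines),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$day <- occasions$day[design$occ]
  design$stage_tag <- occasions$stage_tag[design$occ]
  stressed <- design$plant <= cfg$n_plants_per_arm
  design$arm <- ifelse(stressed, "stress", "control")
  design$treatment <- ifelse(!stressed, "control",
                             ifelse(design$stage_tag == "rewatering",
                                    "recovery", "stress"))
  design$plant_id <- paste0(design$line_label, "_",
                            ifelse(stressed, "S", "C"),
                            formatC(ifelse(stressed, design$plant,
                                           design$plant - cfg$n_plants_per_arm),
                                    width = 2, flag = "0"))
  n <- nrow(design)
  # per-(plant, leaf) random effect, constant across days and replicates
  leaf_key <- paste(design$plant_id, design$leaf_index)
  u <- draw_shared_effect(leaf_key, 0, cfg$leaf_effect_sd)
  # per-(plant, occasion) drought-progression jitter, shared by all leaves
  # and replicates of a plant on one occasion
  occ_key <- paste(design$plant_id, design$stage_tag, design$day)
  jit <- draw_shared_effect(occ_key, 0, cfg$progression_jitter_sd)
  a <- stats::rnorm(n, 0, cfg$scatter_offset_sd)
  b <- stats::rnorm(n, 1, cfg$scatter_slope_sd)
  p <- length(cfg$grid)
  # per-spectrum effective drought days (0 for controls)
  eff0 <- mapply(effective_days, design$day, design$treatment,
                 design$line_label, MoreArgs = list(cfg = cfg))
  eff <- eff0 * (1 + jit)
  # amplitude matrix n x n_bands, then render through the Gaussian basis
  nb <- nrow(cfg$bands)
  amp <- matrix(rep(cfg$bands$base, each = n), n, nb) +
    outer(eff, cfg$bands$slope * cfg$day_slope_scale)
  amp <- pmax(amp, 0)
  rec <- design$treatment == "recovery"
  if (any(rec))
    amp[rec, ] <- sweep(amp[rec, , drop = FALSE], 2,
                        ifelse(cfg$bands$center > 1500, cfg$recovery_extra, 0),
                        `+`)
  amp <- amp * (1 + u)  # leaf effect scales band amplitudes, not baseline
  G <- exp(-outer(cfg$bands$center, cfg$grid, function(cn, lam)
    (lam - cn)^2) / (2 * cfg$bands$width^2))
  A <- amp %*% G + matrix(synth_baseline(cfg$grid), n, p, byrow = TRUE)
  noise <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
  A <- A * b + a + noise
  i1409 <- which.min(abs(cfg$bands$center - 1409.843))
  meta <- tibble::tibble(
    spectrum_id = sprintf("sp%04d", seq_len(n)),
    line_label = design$line_label,
    plant_id = design$plant_id,
    leaf_index = design$leaf_index,
    replicate = design$replicate,
    treatment = design$treatment,
    day = design$day,
    stage_tag = design$stage_tag)
  truth <- tibble::tibble(
    spectrum_id = meta$spectrum_id,
    effective_days = eff,
    free_water_amplitude = amp[, i1409],
    scatter_offset = a, scatter_slope = b, leaf_effect = u,
    progression_jitter = jit,
    day_signal = amp[, i1409] / (1 + u) - cfg$bands$base[i1409])
  list(spectra = spectra_set(cfg$grid, A, meta), truth = truth)
}

draw_shared_effect <- function(key, mean, sd) {
  levels <- unique(key)
  eff <- stats::rnorm(length(levels), mean, sd)
  names(eff) <- levels
  unname(eff[key])
}

#' Closed-form irreducible drought-day prediction error
#'
#' The generator's drought signal for a stressed plant on day `d` is
#' proportional to `max(0, d - onset) * (1 + jitter)`. Even a perfect model
#' of the spectra can therefore only recover the jittered progression: the
#' attainable root-mean-square day error over the stress schedule is
#' `sqrt(mean_d(err_d^2))` where `err_d = (d - onset) * jitter_sd` for days
#' past onset and, for the pre-onset days (indistinguishable from each
#' other), the spread around their common mean. Used to benchmark the PLS
#' calibration: its SECV should land within a modest factor of this bound.
#'
#' @param cfg A `generator_config`.
#' @param line Line label.
#' @return RMS day error (days).
#' @export
expected_day_rmse <- function(cfg, line) {
  onset <- cfg$lines[[line]]
  d <- cfg$stress_days
  flat <- d[d <= onset]
  err2 <- ifelse(d <= onset, (d - mean(flat))^2,
                 ((d - onset) * cfg$progression_jitter_sd)^2)
  sqrt(mean(err2))
}
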