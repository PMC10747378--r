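test_that("default grid carries every WAMAC exactly and stays uniform-ish", {
  grid <- default_grid()
  expect_true(all(default_wamacs()$wavelength %in% grid))
  expect_false(is.unsorted(grid, strictly = TRUE))
  steps <- diff(grid)
  expect_true(all(abs(steps - 6.1945) < 0.05))
  expect_gt(min(grid), 900)
  expect_lt(max(grid), 1675)
})

test_that("band amplitude trajectories follow the linear-after-onset model", {
  cfg <- generator_config()
  base <- cfg$bands$base
  i1409 <- which.min(abs(cfg$bands$center - 1409.843))
  # control: baseline on every day
  expect_equal(band_amplitudes(17, "control", "sensitive", cfg), base)
  # tolerant line at its onset day: still at baseline
  expect_equal(band_amplitudes(7, "stress", "tolerant", cfg), base)
  # sensitive line day 17: closed form base + slope*(17-3)
  got <- band_amplitudes(17, "stress", "sensitive", cfg)
  expect_equal(got, pmax(0, base + cfg$bands$slope * 14))
  expect_equal(got[i1409], base[i1409] - 0.010 * 14)
  # recovery holds the day-17 state, with extra bound water above 1500 nm
  rec <- band_amplitudes(3, "recovery", "sensitive", cfg)
  stress17 <- band_amplitudes(17, "stress", "sensitive", cfg)
  hi <- cfg$bands$center > 1500
  expect_equal(rec[!hi], stress17[!hi])
  expect_equal(rec[hi], stress17[hi] + cfg$recovery_extra)
  expect_error(band_amplitudes(3, "thirsty", "sensitive", cfg), "treatment")
  expect_error(band_amplitudes(3, "stress", "maize", cfg), "line")
})

test_that("rendering is a superposition of Gaussian bands over the baseline", {
  cfg <- generator_config()
  zero <- render_spectrum(rep(0, nrow(cfg$bands)), cfg)
  expect_equal(zero, aqualeaf:::synth_baseline(cfg$grid))
  # single band evaluated at its centre: baseline + amplitude
  amps <- rep(0, nrow(cfg$bands))
  i1409 <- which.min(abs(cfg$bands$center - 1409.843))
  amps[i1409] <- 1
  one <- render_spectrum(amps, cfg)
  j <- nearest_band_index(cfg$grid, cfg$bands$center[i1409])
  expect_equal(one[j], zero[j] + 1, tolerance = 1e-12)
  # linear superposition of two far-separated bands
  a1 <- rep(0, nrow(cfg$bands)); a1[1] <- 0.5      # 930 nm
  a2 <- rep(0, nrow(cfg$bands)); a2[i1409] <- 0.8
  expect_equal(render_spectrum(a1 + a2, cfg),
               render_spectrum(a1, cfg) + render_spectrum(a2, cfg) -
                 aqualeaf:::synth_baseline(cfg$grid), tolerance = 1e-12)
})

test_that("the default design produces the full crossed experiment", {
  g <- generate_experiment(generator_config(seed = 5))
  s <- g$spectra
  expect_equal(n_spectra(s), 2 * 20 * 3 * 8 * 3)   # 2880
  expect_equal(nrow(g$truth), n_spectra(s))
  m <- s$meta
  expect_setequal(unique(m$line_label), c("sensitive", "tolerant"))
  expect_setequal(unique(m$leaf_index), 2:4)
  expect_setequal(unique(m$replicate), 1:3)
  expect_setequal(unique(m$treatment), c("control", "stress", "recovery"))
  expect_setequal(unique(m$day[m$treatment == "stress"]),
                  c(3, 7, 10, 12, 14, 17))
  expect_setequal(unique(m$day[m$treatment == "recovery"]), c(3, 4))
  # 10 stressed + 10 control plants per line
  per_line <- table(unique(m[c("line_label", "plant_id")])$line_label)
  expect_true(all(per_line == 20))
})

test_that("generation is deterministic in the seed", {
  g1 <- generate_experiment(small_generator(seed = 123))
  g2 <- generate_experiment(small_generator(seed = 123))
  expect_identical(g1$spectra$absorbance, g2$spectra$absorbance)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_experiment(small_generator(seed = 124))
  expect_false(identical(g1$spectra$absorbance, g3$spectra$absorbance))
})

test_that("noise-free spectra equal their deterministic renders", {
  cfg <- small_generator(seed = 9, noise_sd = 0, scatter_slope_sd = 0,
                         scatter_offset_sd = 0, leaf_effect_sd = 0,
                         progression_jitter_sd = 0)
  g <- generate_experiment(cfg)
  s <- g$spectra
  i <- which(s$meta$treatment == "stress" & s$meta$day == 17 &
               s$meta$line_label == "sensitive")[1]
  expected <- render_spectrum(
    band_amplitudes(17, "stress", "sensitive", cfg), cfg)
  expect_equal(s$absorbance[i, ], expected, tolerance = 1e-12)
})

test_that("MSC halves the replicate-level scatter in total absorbance", {
  g <- generate_experiment(small_generator(seed = 17))
  s <- g$spectra
  cov_of <- function(A) {
    tot <- rowSums(A)
    grp <- paste(s$meta$plant_id, s$meta$leaf_index, s$meta$stage_tag,
                 s$meta$day)
    mean(tapply(tot, grp, sd) / abs(tapply(tot, grp, mean)))
  }
  raw_cov <- cov_of(s$absorbance)
  msc_cov <- cov_of(msc_fit_transform(s)$corrected$absorbance)
  expect_lt(msc_cov, 0.5 * raw_cov)
})

test_that("invalid generator configs are rejected with named issues", {
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(lines = c(sensitive = 5)), "onset")
  cfg <- generator_config()
  cfg$bands$width[1] <- -2
  expect_gt(length(validate_generator_config(cfg)), 0)
})
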