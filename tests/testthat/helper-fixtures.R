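# Shared fixtures, built in code at test time.

toy_meta <- function(n) {
  tibble::tibble(
    spectrum_id = paste0("s", seq_len(n)),
    line_label = "sensitive",
    plant_id = paste0("p", rep_len(1:2, n)),
    leaf_index = rep_len(2:4, n),
    replicate = rep_len(1:3, n),
    treatment = rep_len(c("control", "stress"), n),
    day = rep_len(c(3, 7, 10), n),
    stage_tag = "drought")
}

toy_spectra <- function(n = 6, p = 20, seed = 42) {
  set.seed(seed)
  wl <- seq(1300, by = 6.2, length.out = p)
  spectra_set(wl, matrix(rnorm(n * p, 0.4, 0.05), n, p), toy_meta(n))
}

# reduced-size experiment for fast module tests
small_generator <- function(seed = 7, ...) {
  generator_config(n_plants_per_arm = 3L, seed = seed, ...)
}
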