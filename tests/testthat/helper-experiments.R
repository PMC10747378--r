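# Full-size experiments are reused across acceptance blocks; cache them per
# seed so each is generated once per test run.
.experiment_cache <- new.env(parent = emptyenv())

full_experiment <- function(seed) {
  key <- as.character(seed)
  if (is.null(.experiment_cache[[key]]))
    .experiment_cache[[key]] <- generate_experiment(generator_config(seed = seed))
  .experiment_cache[[key]]
}

# stress-arm second-derivative spectra restricted to the PLS window
stress_pls_input <- function(spectra, line) {
  d2 <- sg_derivative(spectra, sg_config())
  d2w <- select_wavelength_range(d2, 1300, 1600)
  subset_spectra(d2w, treatment == "stress" & line_label == line)
}
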