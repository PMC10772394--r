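# Shared small-scale simulation settings for unit tests.

small_sim <- function(seed = 42L, ...) {
  sim_config(n_patients = 120L, n_analytes = 20L, n_arrays = 2L,
             seed = seed, ...)
}

small_cfg <- function(seed = 42L, ...) {
  pipeline_config(n_subsamples = 100L, seed = seed,
                  min_shared_analytes = 2L, ...)
}

# A tiny hand-rolled clinical table.
toy_clinical <- function(n = 8L) {
  validate_clinical(data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    hr = rep(c("pos", "neg"), length.out = n),
    her2 = rep(c("neg", "neg", "pos", "pos"), length.out = n),
    arm = rep(c("Ctr", "N"), length.out = n),
    pcr = rep(c(0L, 1L), length.out = n),
    array_id = "array_1",
    stringsAsFactors = FALSE
  ))
}
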