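# Lazily built shared fixtures: the default 60-hook study dataset and its
# normalized coefficients, generated once per test run.

.study_cache <- new.env(parent = emptyenv())

study_dataset <- function() {
  if (is.null(.study_cache$ds)) {
    .study_cache$ds <- generate_dataset(design_spec(seed = 42L))
  }
  .study_cache$ds
}

study_efds <- function() {
  if (is.null(.study_cache$efds)) {
    .study_cache$efds <- run_efd_pipeline(study_dataset()$outlines)$efds
  }
  .study_cache$efds
}

study_morphospace <- function() {
  if (is.null(.study_cache$ms)) {
    .study_cache$ms <- run_morphospace_pipeline(study_efds(),
                                                study_dataset()$metadata)
  }
  .study_cache$ms
}

sample_hooks <- function(k = 10L, n_points = 256L, seed = 7L) {
  kappas <- seq(0.6, 2.4, length.out = k)
  taus <- seq(0.15, 0.35, length.out = k)
  lapply(seq_len(k), function(i) {
    generate_hook(hook_params(kappa = kappas[i], tau = taus[(i %% k) + 1L],
                              noise_sd = 0.003, seed = seed + i),
                  n_points = n_points)
  })
}

# recovery study shared by the parameter-recovery and trajectory checks
acceptance_recovery <- function() {
  if (is.null(.study_cache$recovery)) {
    .study_cache$recovery <- recovery_study(seed = 42L)
  }
  .study_cache$recovery
}
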