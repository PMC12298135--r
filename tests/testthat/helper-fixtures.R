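# Heavy shared fixtures (multistart TPM fits over cohorts), computed once per
# test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 10 pig sessions, TPM truth, fitted with 10 restarts; noise-free or at the
# generator's default noise model.
recovery_fits <- function(noisy = FALSE) {
  fixture(paste0("recovery_", noisy), function() {
    nm <- if (noisy) noise_model() else no_noise()
    co <- generate_cohort(10, "pig", seed = 777, noise = nm)
    fits <- lapply(seq_len(10), function(i) {
      fit_tpm(co$sessions[[i]], n_restarts = 10, seed = 1000 + i)
    })
    list(cohort = co, fits = fits)
  })
}

# 20 pig sessions at uniform 1% CV for the ultrafiltration comparison.
uf_fits <- function() {
  fixture("uf", function() {
    co <- generate_cohort(20, "pig", seed = 20,
                          noise = noise_model(0.01, 0.01, 0.01, 0.01))
    fits <- lapply(seq_len(20), function(i) {
      fit_tpm(co$sessions[[i]], n_restarts = 10, seed = 2000 + i)
    })
    list(cohort = co, fits = fits)
  })
}

# Noise-free TPM-generated 5-session pig cohort benchmarked with all models.
benchmark_report_fixture <- function() {
  fixture("bench", function() {
    co <- generate_cohort(5, "pig", seed = 888, noise = no_noise())
    run_benchmark(co$sessions, models = pd_models(), seed = 11)
  })
}
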