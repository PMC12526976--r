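# Shared fixtures and memoised heavy computations. The pipeline-scale runs
# are shared between the end-to-end and stability checks, which both draw on
# the same standard corrupted recording conditions.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# standard corrupted fixture: 10 s at 1 kHz, 50 Hz line pickup, 0.2 Hz
# drift, broadband noise (generator defaults)
standard_fixture <- function(seed = 42L) {
  memo(paste0("fixture_", seed), {
    cfg <- mcg_sim_config(seed = seed)
    clean <- generate_clean_mcg(cfg)
    list(cfg = cfg, clean = clean, raw = corrupt_signal(clean, cfg))
  })
}

# optimizer budget for pipeline-scale tests: population and iteration count
# scaled to a quarter of the full study configuration (15/12 vs 60/50)
pipeline_aoa_cfg <- function(seed = 7L) {
  aoa_config(pop_size = 15, max_iter = 12,
             lower = c(4, 500), upper = c(10, 3000),
             integer_dims = 1L, seed = seed)
}

# pipeline + comparator denoisers, evaluated per fixture seed
pipeline_run <- function(noise_seed) {
  memo(paste0("pipeline_", noise_seed), {
    fx <- standard_fixture(noise_seed)
    res <- denoise_mcg(fx$raw, pipeline_aoa_cfg(seed = noise_seed))
    mets <- list(aovmd = evaluate_denoising(fx$raw, res$denoised))
    mets$fir <- evaluate_denoising(fx$raw, fir_denoise(fx$raw))
    mets$wt_soft <- evaluate_denoising(fx$raw, wavelet_baseline(fx$raw, "soft"))
    mets$wt_hard <- evaluate_denoising(fx$raw, wavelet_baseline(fx$raw, "hard"))
    list(fit = res, metrics = mets)
  })
}

stability_table <- function() {
  memo("stability", {
    fx <- standard_fixture(42L)
    stability_runs(fx$raw, n_runs = 10, base_seed = 101L,
                   aoa_cfg = pipeline_aoa_cfg())
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * max(abs(expected), 1e-300))
}
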