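test_that("modes are classified by centre frequency with default cutoffs", {
  plan <- classify_modes(c(0.2, 10, 80), disposal_config())
  expect_equal(plan$action, c("baseline", "wavelet", "remove"))
  # pure function of (center_freqs, config): identical on repeat
  expect_identical(plan, classify_modes(c(0.2, 10, 80), disposal_config()))
  expect_error(classify_modes(numeric(), disposal_config()), "empty")
})

test_that("every mode receives exactly one action", {
  set.seed(9)
  for (i in 1:10) {
    fc <- sort(runif(5, 0, 120))
    plan <- classify_modes(fc, disposal_config())
    expect_equal(nrow(plan), 5L)
    expect_true(all(plan$action %in% c("remove", "wavelet", "baseline")))
  }
})

test_that("the lowest retained mode falls back to baseline treatment", {
  plan <- classify_modes(c(2, 10, 80), disposal_config())
  expect_equal(plan$action, c("baseline", "wavelet", "remove"))
  plan2 <- classify_modes(c(2, 10, 80),
                          disposal_config(baseline_lowest_fallback = FALSE))
  expect_equal(plan2$action, c("wavelet", "wavelet", "remove"))
})

test_that("baseline correction removes offsets and slow drift", {
  fs <- 500
  const <- rep(3.7, 4000)
  out <- correct_baseline(const, fs, disposal_config())
  expect_lt(max(abs(out)), 1e-9)

  expect_true(all(correct_baseline(rep(0, 4000), fs, disposal_config()) == 0))

  cfg <- mcg_sim_config(fs = fs, duration = 10, powerline_amp = 0,
                        white_sigma = 0, drift_amp = 0)
  bumps <- signal_values(generate_clean_mcg(cfg))
  t <- (seq_along(bumps) - 1) / fs
  drifted <- bumps + 0.5 * sin(2 * pi * 0.2 * t)
  for (method in c("median", "highpass", "polynomial")) {
    corr <- correct_baseline(drifted, fs,
                             disposal_config(baseline_method = method))
    expect_lt(abs(mean(corr)), 1e-8 * (sd(drifted) + 1e-30))
    p_before <- band_power(mcg_signal(drifted, fs), c(0, 0.5))
    p_after <- band_power(mcg_signal(corr, fs), c(0, 0.5))
    # a cubic cannot track two full drift cycles; it must still improve
    expect_gt(10 * log10(p_before / p_after),
              if (method == "polynomial") 0 else 10)
  }
})

test_that("a short record falls back to mean subtraction with a warning", {
  expect_warning(out <- correct_baseline(rnorm(100) + 5, 1000,
                                         disposal_config()),
                 "mean")
  expect_lt(abs(mean(out)), 1e-10)
})

test_that("disposal removes a high-frequency tone from the reconstruction", {
  mix <- generate_tone_mixture(c(10, 80), c(1, 0.5), fs = 400, duration = 5)
  d <- vmd_decompose(mix, vmd_params(K = 2, alpha = 2000))
  disp <- apply_disposal(d, disposal_config())
  expect_equal(disp$plan$action[disp$plan$center_freq_hz > 50], "remove")
  p_in <- band_power(mix, c(79, 81))
  p_out <- band_power(disp$denoised, c(79, 81))
  expect_gt(10 * log10(p_in / p_out), 20)
  # reconstruction additivity: output is exactly the sum of processed modes
  keep <- disp$plan$action != "remove"
  expect_equal(signal_values(disp$denoised),
               rowSums(disp$processed[, keep, drop = FALSE]), tolerance = 0)
})

test_that("disposal errors when every mode would be removed", {
  mix <- generate_tone_mixture(c(60, 80), c(1, 1), fs = 400, duration = 2)
  d <- vmd_decompose(mix, vmd_params(K = 2, alpha = 2000))
  expect_error(apply_disposal(d, disposal_config(f_base = 0.5, f_high = 20,
                                                 baseline_lowest_fallback = FALSE)),
               "no modes retained")
})

test_that("near-identity on a clean signal", {
  cfg <- mcg_sim_config(fs = 250, duration = 8, powerline_amp = 0,
                        drift_amp = 0, white_sigma = 0)
  clean <- generate_clean_mcg(cfg)
  res <- denoise_mcg(clean,
                     aoa_config(pop_size = 8, max_iter = 6,
                                lower = c(4, 500), upper = c(10, 3000),
                                integer_dims = 1L, seed = 3L))
  expect_gte(cor(signal_values(res$denoised), signal_values(clean)), 0.99)
})

test_that("the study search ranges are accepted and reported", {
  fx <- standard_fixture(42L)
  run <- pipeline_run(42L)
  expect_true(run$fit$K >= 4 && run$fit$K <= 10)
  expect_true(run$fit$alpha >= 500 && run$fit$alpha <= 3000)
  m <- run$metrics$aovmd
  expect_gt(m$hfnsa_db, 0)
  expect_gt(m$lfnsa_db, 0)
  g <- glance(run$fit)
  expect_equal(g$K, run$fit$K)
  expect_identical(tidy(run$fit), run$fit$plan)
})
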