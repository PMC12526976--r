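# Independent naive reimplementations of the metric formulas (direct DFT,
# explicit loops) used as oracles against the package implementations.

naive_psd <- function(x, fs) {
  n <- length(x)
  half <- floor(n / 2) + 1L
  psd <- numeric(half)
  idx <- 0:(n - 1)
  for (k in seq_len(half)) {
    w <- 2 * pi * (k - 1) * idx / n
    re <- sum(x * cos(w))
    im <- -sum(x * sin(w))
    psd[k] <- (re^2 + im^2) / (fs * n)
  }
  if (n %% 2 == 0) {
    psd[2:(half - 1)] <- 2 * psd[2:(half - 1)]
  } else {
    psd[2:half] <- 2 * psd[2:half]
  }
  list(freq = (seq_len(half) - 1L) * fs / n, psd = psd)
}

naive_band_power <- function(x, fs, band) {
  sp <- naive_psd(x, fs)
  df <- fs / length(x)
  sum(sp$psd[sp$freq > band[1] & sp$freq <= band[2] + 1e-12]) * df
}

naive_spectral_entropy <- function(x, fs, eps = 1e-12) {
  sp <- naive_psd(x, fs)
  tot <- sum(sp$psd)
  h <- 0
  for (p in sp$psd / tot) h <- h - p * log10(p + eps)
  h
}

pg_cfg <- metrics_config(psd_method = "periodogram")

test_that("band power concentrates where the tone is", {
  tone <- generate_tone_mixture(50, 1, fs = 1000, duration = 10)
  total <- band_power(tone, c(0, 500))
  expect_gt(band_power(tone, c(40, 500)) / total, 0.95)
  expect_lt(band_power(tone, c(0, 0.5)) / total, 0.01)
  zero <- mcg_signal(c(0, rep(0, 999)), fs = 1000)
  expect_equal(band_power(zero, c(40, 500)), 0)
  expect_error(band_power(tone, c(10, 5)), "band")
})

test_that("suppression metrics give exact values on constructed ratios", {
  fx <- standard_fixture(42L)
  raw <- fx$raw
  expect_equal(hfnsa(raw, raw), 0)
  expect_equal(lfnsa(raw, raw), 0)
  scaled10 <- new_sig <- mcg_signal(signal_values(raw) / sqrt(10),
                                    signal_fs(raw))
  expect_equal(hfnsa(raw, scaled10), 10, tolerance = 1e-9)
  scaled100 <- mcg_signal(signal_values(raw) / 10, signal_fs(raw))
  expect_equal(hfnsa(raw, scaled100), 20, tolerance = 1e-9)
  expect_equal(lfnsa(raw, scaled100), 20, tolerance = 1e-9)
})

test_that("suppression formulas match the naive DFT oracle on random pairs", {
  set.seed(31)
  fs <- 256
  for (i in 1:100) {
    a <- rnorm(512) + sin(2 * pi * runif(1, 1, 100) * (0:511) / fs)
    b <- 0.5 * a + 0.2 * rnorm(512)
    sa <- mcg_signal(a, fs); sb <- mcg_signal(b, fs)
    hf <- 10 * log10(naive_band_power(a, fs, c(40, fs / 2)) /
                     naive_band_power(b, fs, c(40, fs / 2)))
    lf <- 10 * log10(naive_band_power(a, fs, c(0, 0.5)) /
                     naive_band_power(b, fs, c(0, 0.5)))
    expect_rel_equal(hfnsa(sa, sb, pg_cfg), hf, 1e-9)
    expect_rel_equal(lfnsa(sa, sb, pg_cfg), lf, 1e-9)
    expect_rel_equal(spectral_entropy(sa, pg_cfg),
                     naive_spectral_entropy(a, fs), 1e-9)
  }
})

test_that("R peaks are found at the generator's beat positions", {
  cfg <- mcg_sim_config(fs = 1000, duration = 10, powerline_amp = 0,
                        drift_amp = 0, white_sigma = 0)
  clean <- generate_clean_mcg(cfg)
  peaks <- detect_r_peaks(clean)
  expect_true(abs(length(peaks) - 10L) <= 1L)
  gaps <- diff(peaks)
  expect_true(all(abs(gaps - 1000) <= 50))
  expect_warning(z <- detect_r_peaks(mcg_signal(rep(0, 5000), 1000)), "zero")
  expect_length(z, 0)
})

test_that("QRS amplitude change is exact under homogeneous scaling", {
  cfg <- mcg_sim_config(fs = 500, duration = 8, powerline_amp = 0,
                        drift_amp = 0, white_sigma = 0)
  clean <- generate_clean_mcg(cfg)
  expect_equal(qrs_amplitude_change(clean, clean), 0)
  shrunk <- mcg_signal(0.8 * signal_values(clean), 500)
  expect_equal(qrs_amplitude_change(clean, shrunk), -20, tolerance = 1e-9)
  grown <- mcg_signal(1.1 * signal_values(clean), 500)
  expect_equal(qrs_amplitude_change(clean, grown), 10, tolerance = 1e-9)
})

test_that("QRS amplitude matches an explicit window loop on noisy beats", {
  set.seed(13)
  fs <- 250
  for (i in 1:10) {
    amps <- c(P = runif(1, 0.1, 0.2), Q = -0.1, R = runif(1, 0.8, 1.4),
              S = -0.2, T = 0.3)
    cfg <- mcg_sim_config(fs = fs, duration = 6, wave_amplitudes = amps,
                          powerline_amp = 0, drift_amp = 0, white_sigma = 0,
                          seed = i)
    raw <- generate_clean_mcg(cfg)
    den <- mcg_signal(signal_values(raw) * 0.9 + 0.01 * rnorm(nrow(raw)), fs)
    peaks <- detect_r_peaks(raw)
    w <- round(0.06 * fs)
    amp_of <- function(x) {
      tot <- 0
      for (p in peaks) {
        lo <- max(1, p - w); hi <- min(length(x), p + w)
        tot <- tot + (max(x[lo:hi]) - min(x[lo:hi]))
      }
      tot / length(peaks)
    }
    a_raw <- amp_of(signal_values(raw))
    a_den <- amp_of(signal_values(den))
    expect_rel_equal(qrs_amplitude_change(raw, den),
                     (a_den - a_raw) / a_raw * 100, 1e-9)
  }
})

test_that("spectral entropy behaves like a concentration measure", {
  n <- 1000L
  expect_equal(spectral_entropy_from_psd(rep(1, n)), log10(n),
               tolerance = 1e-6)
  expect_lt(abs(spectral_entropy_from_psd(c(rep(0, n - 1), 1))), 1e-6)
  expect_equal(spectral_entropy_from_psd(c(1, 1)), log10(2),
               tolerance = 1e-6)
  expect_error(spectral_entropy_from_psd(rep(0, 4)), "all-zero")
})

test_that("metrics are invariant to common rescaling of both signals", {
  fx <- standard_fixture(42L)
  raw <- fx$raw
  den <- fir_denoise(raw)
  sraw <- mcg_signal(3.5 * signal_values(raw), signal_fs(raw))
  sden <- mcg_signal(3.5 * signal_values(den), signal_fs(den))
  expect_equal(hfnsa(sraw, sden), hfnsa(raw, den), tolerance = 1e-9)
  expect_equal(lfnsa(sraw, sden), lfnsa(raw, den), tolerance = 1e-9)
  expect_equal(qrs_amplitude_change(sraw, sden),
               qrs_amplitude_change(raw, den), tolerance = 1e-9)
  expect_equal(spectral_entropy(sraw), spectral_entropy(raw),
               tolerance = 1e-6)
})

test_that("the residual is the exact sample-wise difference", {
  fx <- standard_fixture(42L)
  den <- fir_denoise(fx$raw)
  res <- residual_signal(fx$raw, den)
  expect_equal(signal_values(res) + signal_values(den),
               signal_values(fx$raw), tolerance = 1e-12)
  expect_equal(signal_values(residual_signal(fx$raw, fx$raw)),
               rep(0, nrow(fx$raw)))
  short <- mcg_signal(rnorm(100), signal_fs(fx$raw))
  expect_error(residual_signal(fx$raw, short), "length")
})

test_that("the identity pair yields an all-zero report that round-trips JSON", {
  cfg <- mcg_sim_config(fs = 500, duration = 6, white_sigma = 0.02)
  raw <- corrupt_signal(generate_clean_mcg(cfg), cfg)
  rep <- evaluate_denoising(raw, raw)
  expect_equal(rep$hfnsa_db, 0)
  expect_equal(rep$lfnsa_db, 0)
  expect_equal(rep$qrsa_pct, 0)
  expect_equal(rep$spectral_entropy_raw, rep$spectral_entropy_denoised)

  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, path)
  back <- read_metrics_json(path)
  expect_equal(back$hfnsa_db, rep$hfnsa_db, tolerance = 1e-12)
  expect_equal(back$spectral_entropy_raw, rep$spectral_entropy_raw,
               tolerance = 1e-12)
  expect_equal(back$r_peaks_raw, rep$r_peaks_raw)

  td <- tidy(rep)
  expect_equal(names(td), c("hfnsa_db", "lfnsa_db", "qrsa_pct",
                            "spectral_entropy_raw",
                            "spectral_entropy_denoised"))
})
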