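#' Configuration for denoising quality metrics
#'
#' @param high_band Hz interval counted as high-frequency noise; the upper
#'   edge `NA` resolves to the Nyquist frequency at use time.
#' @param low_band Hz interval counted as low-frequency (baseline) noise.
#' @param psd_method `"welch"` (Hann window, 2 s segments, 50% overlap;
#'   default) or `"periodogram"` (single rectangular-window segment).
#' @param welch_seg_s Welch segment length in seconds.
#' @param entropy_eps Small positive constant added inside the logarithm of
#'   the spectral entropy so empty bins contribute nothing.
#' @param rpeak_band Bandpass interval (Hz) used by the R-peak detector.
#' @return A list of class `metrics_config`.
#' @export
metrics_config <- function(high_band = c(40, NA), low_band = c(0, 0.5),
                           psd_method = c("welch", "periodogram"),
                           welch_seg_s = 2, entropy_eps = 1e-12,
                           rpeak_band = c(5, 25)) {
  psd_method <- match.arg(psd_method)
  if (entropy_eps <= 0) abort("`entropy_eps` must be > 0.",
                              class = "aovmd_config_error")
  structure(list(high_band = high_band, low_band = low_band,
                 psd_method = psd_method, welch_seg_s = welch_seg_s,
                 entropy_eps = entropy_eps, rpeak_band = rpeak_band),
            class = "metrics_config")
}

#' Power spectral density estimate
#'
#' One-sided PSD by Welch's method (Hann window, 50% overlap) or a plain
#' periodogram.
#'
#' @param signal An [mcg_signal()] or numeric vector with `fs`.
#' @param cfg A [metrics_config()].
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return A tibble with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
psd_estimate <- function(signal, cfg = metrics_config(), fs = NULL) {
  signal <- as_mcg_signal(signal, fs = fs)
  x <- signal_values(signal)
  fs <- signal_fs(signal)
  n <- length(x)
  if (cfg$psd_method == "periodogram") {
    seg_len <- n
    win <- rep(1, n)
    starts <- 1L
  } else {
    seg_len <- min(n, round(cfg$welch_seg_s * fs))
    if (seg_len < 8L) seg_len <- n
    k <- seq_len(seg_len) - 1L
    win <- 0.5 * (1 - cos(2 * pi * k / (seg_len - 1)))
    step <- max(1L, floor(seg_len / 2))
    starts <- seq(1L, n - seg_len + 1L, by = step)
  }
  u <- sum(win^2)
  half <- floor(seg_len / 2) + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * win
    sp <- abs(fft(seg))^2 / (fs * u)
    p <- sp[seq_len(half)]
    # fold negative frequencies into the one-sided estimate
    if (seg_len %% 2 == 0) {
      p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
    } else {
      p[2:half] <- 2 * p[2:half]
    }
    acc <- acc + p
  }
  tibble::tibble(freq = (seq_len(half) - 1L) * fs / seg_len,
                 psd = acc / length(starts))
}

resolve_band <- function(band, fs) {
  if (is.na(band[2])) band[2] <- fs / 2
  if (band[1] < 0 || band[2] > fs / 2 + 1e-9 || band[1] >= band[2]) {
    abort("band must be a nonempty interval within (0, fs/2].",
          class = "aovmd_config_error")
  }
  band
}

#' Signal power within a frequency band
#'
#' Integral of the PSD estimate over `(band[1], band[2]]` (Riemann sum on
#' the discrete frequency grid; the DC bin is excluded when the lower edge
#' is 0).
#'
#' @param signal An [mcg_signal()].
#' @param band Length-2 Hz interval.
#' @param cfg A [metrics_config()].
#' @return Nonnegative power.
#' @export
band_power <- function(signal, band, cfg = metrics_config()) {
  signal <- as_mcg_signal(signal)
  band <- resolve_band(band, signal_fs(signal))
  spec <- psd_estimate(signal, cfg)
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq > band[1] & spec$freq <= band[2] + 1e-12
  sum(spec$psd[sel]) * df
}

suppression_db <- function(raw, denoised, band, cfg) {
  check_same_grid(raw, denoised)
  p_raw <- band_power(raw, band, cfg)
  p_den <- band_power(denoised, band, cfg)
  if (p_raw <= 0) abort("raw band power is zero; suppression undefined.",
                        class = "aovmd_config_error")
  if (p_den == 0) {
    warn("denoised band power is zero; suppression is infinite.")
    return(Inf)
  }
  10 * log10(p_raw / p_den)
}

#' High-frequency noise suppression amount (dB)
#'
#' `10 * log10(P_high_raw / P_high_denoised)` over the high band (default
#' above 40 Hz). Positive values mean suppression.
#'
#' @param raw,denoised Paired [mcg_signal()]s on the same grid.
#' @param cfg A [metrics_config()].
#' @return Suppression in dB.
#' @export
hfnsa <- function(raw, denoised, cfg = metrics_config()) {
  suppression_db(as_mcg_signal(raw), as_mcg_signal(denoised), cfg$high_band, cfg)
}

#' Low-frequency noise suppression amount (dB)
#'
#' As [hfnsa()] but over the low band (default below 0.5 Hz), capturing
#' baseline-drift removal.
#'
#' @inheritParams hfnsa
#' @return Suppression in dB.
#' @export
lfnsa <- function(raw, denoised, cfg = metrics_config()) {
  suppression_db(as_mcg_signal(raw), as_mcg_signal(denoised), cfg$low_band, cfg)
}

#' Detect R peaks
#'
#' Pan-Tompkins-style detector: zero-phase bandpass (default 5-25 Hz),
#' squaring, 150 ms moving-window integration, and an adaptive
#' signal/noise threshold with a 200 ms refractory period. Peak positions
#' are refined to the local maximum of the bandpassed signal.
#'
#' @param signal An [mcg_signal()] longer than 2 s.
#' @param cfg A [metrics_config()].
#' @return Integer vector of R-peak sample indices (possibly empty).
#' @export
detect_r_peaks <- function(signal, cfg = metrics_config()) {
  signal <- as_mcg_signal(signal)
  x <- signal_values(signal)
  fs <- signal_fs(signal)
  if (length(x) < 2 * fs) abort("signal must be longer than 2 s.",
                                class = "aovmd_config_error")
  if (all(x == 0)) {
    warn("zero signal: no R peaks.")
    return(integer())
  }
  bf <- signal::butter(3, cfg$rpeak_band / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))
  sq <- bp^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # candidate local maxima of the integrated energy
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(cand)) {
    warn("no peaks found.")
    return(integer())
  }
  init_n <- min(length(integ), round(2 * fs))
  spki <- 0.5 * max(integ[seq_len(init_n)])
  npki <- 0.5 * mean(integ[seq_len(init_n)])
  refractory <- round(0.2 * fs)
  accepted <- integer()
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] > thr && (i - last) > refractory) {
      accepted <- c(accepted, i)
      last <- i
      spki <- 0.125 * integ[i] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (!length(accepted)) {
    warn("no peaks found.")
    return(integer())
  }
  # refine on the bandpassed waveform
  half_w <- as.integer(round(0.1 * fs))
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, i - half_w)
    hi <- min(length(bp), i + half_w)
    as.integer(lo + which.max(bp[lo:hi]) - 1L)
  }, integer(1))
  sort(unique(peaks))
}

#' QRS amplitude change (percent)
#'
#' Mean peak-to-trough amplitude inside +/-60 ms of each R peak, peaks
#' detected on the raw signal and reused on the denoised one, reported as
#' the signed percentage change `(A_denoised - A_raw) / A_raw * 100`.
#' Values near zero mean the QRS morphology survived denoising.
#'
#' @inheritParams hfnsa
#' @return Signed percentage.
#' @export
qrs_amplitude_change <- function(raw, denoised, cfg = metrics_config()) {
  raw <- as_mcg_signal(raw); denoised <- as_mcg_signal(denoised)
  check_same_grid(raw, denoised)
  fs <- signal_fs(raw)
  peaks <- detect_r_peaks(raw, cfg)
  if (!length(peaks)) abort("no R peaks detectable in the raw signal.",
                            class = "aovmd_config_error")
  amp <- function(x, p) {
    w <- round(0.06 * fs)
    mean(vapply(p, function(i) {
      lo <- max(1L, i - w); hi <- min(length(x), i + w)
      max(x[lo:hi]) - min(x[lo:hi])
    }, numeric(1)))
  }
  a_raw <- amp(signal_values(raw), peaks)
  if (a_raw == 0) abort("raw QRS amplitude is zero.", class = "aovmd_config_error")
  a_den <- amp(signal_values(denoised), peaks)
  (a_den - a_raw) / a_raw * 100
}

#' Spectral entropy of a PSD
#'
#' Shannon entropy (base 10) of the normalized power spectral density with
#' the stabilizing constant inside the logarithm:
#' `-sum(p_i * log10(p_i + eps))`.
#'
#' @param psd Nonnegative PSD values.
#' @param eps Stabilizing constant.
#' @return Nonnegative entropy.
#' @export
spectral_entropy_from_psd <- function(psd, eps = 1e-12) {
  if (any(psd < 0)) abort("PSD must be nonnegative.", class = "aovmd_config_error")
  tot <- sum(psd)
  if (tot == 0) abort("all-zero PSD: entropy undefined.",
                      class = "aovmd_config_error")
  p <- psd / tot
  -sum(p * log10(p + eps))
}

#' Spectral entropy of a signal
#'
#' Lower values indicate a more concentrated, cleaner spectrum.
#'
#' @param signal An [mcg_signal()].
#' @param cfg A [metrics_config()].
#' @return Nonnegative entropy.
#' @export
spectral_entropy <- function(signal, cfg = metrics_config()) {
  spec <- psd_estimate(as_mcg_signal(signal), cfg)
  spectral_entropy_from_psd(spec$psd, cfg$entropy_eps)
}

#' Denoising residual
#'
#' @inheritParams hfnsa
#' @return An [mcg_signal()] equal to `raw - denoised` sample-wise.
#' @export
residual_signal <- function(raw, denoised) {
  raw <- as_mcg_signal(raw); denoised <- as_mcg_signal(denoised)
  check_same_grid(raw, denoised)
  new_signal_like(raw, signal_values(raw) - signal_values(denoised),
                  label = "residual")
}

#' Evaluate a raw/denoised pair
#'
#' Assembles the four quality metrics — high- and low-frequency noise
#' suppression (dB), QRS amplitude change (%), spectral entropy of both
#' signals — together with the residual series and detected R peaks.
#'
#' @inheritParams hfnsa
#' @return Object of class `mcg_metrics`.
#' @export
evaluate_denoising <- function(raw, denoised, cfg = metrics_config()) {
  raw <- as_mcg_signal(raw); denoised <- as_mcg_signal(denoised)
  check_same_grid(raw, denoised)
  structure(list(
    hfnsa_db = hfnsa(raw, denoised, cfg),
    lfnsa_db = lfnsa(raw, denoised, cfg),
    qrsa_pct = qrs_amplitude_change(raw, denoised, cfg),
    spectral_entropy_raw = spectral_entropy(raw, cfg),
    spectral_entropy_denoised = spectral_entropy(denoised, cfg),
    residual = residual_signal(raw, denoised),
    r_peaks_raw = detect_r_peaks(raw, cfg),
    r_peaks_denoised = detect_r_peaks(denoised, cfg),
    config = cfg
  ), class = "mcg_metrics")
}

#' @export
print.mcg_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<mcg_metrics>\n",
    "  HFNSA: %8.3f dB\n  LFNSA: %8.3f dB\n  QRSA:  %8.3f %%\n",
    "  spectral entropy: %.4f (raw) -> %.4f (denoised)\n"),
    x$hfnsa_db, x$lfnsa_db, x$qrsa_pct,
    x$spectral_entropy_raw, x$spectral_entropy_denoised))
  invisible(x)
}

#' @export
tidy.mcg_metrics <- function(x, ...) {
  tibble::tibble(
    hfnsa_db = x$hfnsa_db,
    lfnsa_db = x$lfnsa_db,
    qrsa_pct = x$qrsa_pct,
    spectral_entropy_raw = x$spectral_entropy_raw,
    spectral_entropy_denoised = x$spectral_entropy_denoised
  )
}

#' Write a metrics report to JSON
#'
#' @param x An `mcg_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  out <- list(
    hfnsa_db = x$hfnsa_db, lfnsa_db = x$lfnsa_db, qrsa_pct = x$qrsa_pct,
    spectral_entropy_raw = x$spectral_entropy_raw,
    spectral_entropy_denoised = x$spectral_entropy_denoised,
    r_peaks_raw = x$r_peaks_raw, r_peaks_denoised = x$r_peaks_denoised
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a metrics report back from JSON
#'
#' @param path JSON file written by [write_metrics_json()].
#' @return A named list of metric values.
#' @export
read_metrics_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
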