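#' Configuration for the FIR comparator denoiser
#'
#' @param passband Hz interval retained (default 0.5-40 Hz, bracketing the
#'   cardiac band between the baseline-drift and power-line regions).
#' @param numtaps Filter length (odd).
#' @param window Window name (only `"hamming"` is implemented).
#' @param zero_phase Apply the filter forward-backward.
#' @return A list of class `fir_config`.
#' @export
fir_config <- function(passband = c(0.5, 40), numtaps = 501,
                       window = "hamming", zero_phase = TRUE) {
  if (numtaps %% 2 == 0) abort("`numtaps` must be odd.",
                               class = "aovmd_config_error")
  if (passband[1] <= 0 || passband[1] >= passband[2]) {
    abort("`passband` must be a nonempty interval with positive lower edge.",
          class = "aovmd_config_error")
  }
  window <- match.arg(window, "hamming")
  structure(list(passband = passband, numtaps = as.integer(numtaps),
                 window = window, zero_phase = zero_phase),
            class = "fir_config")
}

#' FIR bandpass comparator denoiser
#'
#' Linear-phase windowed-sinc bandpass, applied forward-backward so the net
#' phase is zero; output length equals input length.
#'
#' @param signal An [mcg_signal()].
#' @param cfg A [fir_config()].
#' @return Denoised [mcg_signal()].
#' @export
fir_denoise <- function(signal, cfg = fir_config()) {
  signal <- as_mcg_signal(signal)
  fs <- signal_fs(signal)
  if (cfg$passband[2] >= fs / 2) {
    abort("passband upper edge must lie below the Nyquist frequency.",
          class = "aovmd_config_error")
  }
  b <- as.numeric(signal::fir1(cfg$numtaps - 1L, cfg$passband / (fs / 2),
                               type = "pass",
                               window = signal::hamming(cfg$numtaps)))
  # a sub-1 Hz lower edge is narrower than the window's transition band, so
  # the windowed design leaves substantial DC gain; re-centre the taps to
  # place an exact spectral null at DC
  b <- b - mean(b)
  x <- signal_values(signal)
  y <- if (cfg$zero_phase) {
    as.numeric(signal::filtfilt(b, 1, x))
  } else {
    as.numeric(signal::filter(signal::Ma(b), x))
  }
  new_signal_like(signal, y, label = "FIR denoised")
}

#' Whole-signal wavelet-threshold comparator denoiser
#'
#' Universal-threshold wavelet shrinkage applied to the full signal (no
#' decomposition front end), with soft or hard thresholding — the classic
#' comparator the adaptive pipeline is judged against.
#'
#' @param signal An [mcg_signal()].
#' @param mode `"soft"` or `"hard"`.
#' @param dcfg A [disposal_config()] supplying the wavelet settings.
#' @return Denoised [mcg_signal()].
#' @export
wavelet_baseline <- function(signal, mode = c("soft", "hard"),
                             dcfg = disposal_config()) {
  mode <- match.arg(mode)
  signal <- as_mcg_signal(signal)
  y <- wavelet_shrink(signal_values(signal), wavelet = dcfg$wavelet_name,
                      levels = dcfg$wavelet_levels, mode = mode)
  new_signal_like(signal, y, label = paste0("WT(", mode, ") denoised"))
}

#' Compare denoising methods on one signal
#'
#' Runs the adaptive pipeline and the comparator denoisers on the same raw
#' trace and evaluates each against the raw signal, producing one row of
#' quality metrics per method.
#'
#' @param signal Raw [mcg_signal()].
#' @param methods Subset of `c("aovmd", "fir", "wt_soft", "wt_hard")`.
#' @param aoa_cfg,vparams,dcfg,ecfg Pipeline configuration (see
#'   [denoise_mcg()]).
#' @param fcfg A [fir_config()].
#' @param mcfg A [metrics_config()].
#' @return A tibble with columns `method`, `hfnsa_db`, `lfnsa_db`,
#'   `qrsa_pct`, `spectral_entropy` (of the denoised trace).
#' @export
compare_denoisers <- function(signal,
                              methods = c("aovmd", "fir", "wt_soft", "wt_hard"),
                              aoa_cfg = aoa_config(integer_dims = 1L),
                              vparams = vmd_params(),
                              dcfg = disposal_config(),
                              ecfg = entropy_config(),
                              fcfg = fir_config(),
                              mcfg = metrics_config()) {
  signal <- as_mcg_signal(signal)
  methods <- match.arg(methods, several.ok = TRUE)
  denoise_one <- function(m) {
    switch(m,
      aovmd = denoise_mcg(signal, aoa_cfg, vparams, dcfg, ecfg)$denoised,
      fir = fir_denoise(signal, fcfg),
      wt_soft = wavelet_baseline(signal, "soft", dcfg),
      wt_hard = wavelet_baseline(signal, "hard", dcfg)
    )
  }
  purrr::map_dfr(methods, function(m) {
    den <- denoise_one(m)
    rep <- evaluate_denoising(signal, den, mcfg)
    tibble::tibble(
      method = m,
      hfnsa_db = rep$hfnsa_db,
      lfnsa_db = rep$lfnsa_db,
      qrsa_pct = rep$qrsa_pct,
      spectral_entropy = rep$spectral_entropy_denoised
    )
  })
}
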