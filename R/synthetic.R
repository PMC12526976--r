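#' Configuration for the synthetic MCG generator
#'
#' Describes a PQRST-like quasi-periodic waveform plus the three structured
#' interference classes seen in unshielded magnetocardiography: power-line
#' pickup, sub-0.5 Hz baseline drift, and broadband sensor noise. Amplitudes
#' are in arbitrary units standing in for picotesla; the default R-wave
#' amplitude of 1 sets the scale.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds.
#' @param heart_rate Beats per minute, in \[30, 200\].
#' @param wave_amplitudes Named numeric vector of peak heights for the
#'   P, Q, R, S, T deflections.
#' @param wave_offsets Named numeric vector of intra-beat centre offsets in
#'   seconds, relative to the R peak.
#' @param wave_widths Named numeric vector of Gaussian widths (sd, seconds)
#'   per wave.
#' @param beat_jitter_sd Standard deviation (s) of Gaussian beat-onset
#'   jitter; 0 gives a strictly periodic train.
#' @param powerline_freq Power-line frequency in Hz, in \[40, 70\].
#' @param powerline_amp Power-line interference amplitude.
#' @param drift_freq Baseline drift frequency in Hz, in (0, 0.5).
#' @param drift_amp Baseline drift amplitude.
#' @param white_sigma Standard deviation of additive white noise.
#' @param seed Integer seed driving all randomness in the generator.
#'
#' @return A list of class `mcg_sim_config`.
#' @export
mcg_sim_config <- function(fs = 1000, duration = 10, heart_rate = 60,
                           wave_amplitudes = c(P = 0.15, Q = -0.1, R = 1,
                                               S = -0.2, T = 0.3),
                           wave_offsets = c(P = -0.17, Q = -0.025, R = 0,
                                            S = 0.025, T = 0.25),
                           wave_widths = c(P = 0.025, Q = 0.012, R = 0.012,
                                           S = 0.012, T = 0.06),
                           beat_jitter_sd = 0,
                           powerline_freq = 50, powerline_amp = 0.3,
                           drift_freq = 0.2, drift_amp = 0.5,
                           white_sigma = 0.1, seed = 1L) {
  cfg <- list(
    fs = fs, duration = duration, heart_rate = heart_rate,
    wave_amplitudes = wave_amplitudes, wave_offsets = wave_offsets,
    wave_widths = wave_widths, beat_jitter_sd = beat_jitter_sd,
    powerline_freq = powerline_freq, powerline_amp = powerline_amp,
    drift_freq = drift_freq, drift_amp = drift_amp,
    white_sigma = white_sigma, seed = as.integer(seed)
  )
  class(cfg) <- "mcg_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "aovmd_config_error")
  }
  if (!is.finite(cfg$fs) || cfg$fs <= 0) bad("fs", "must be > 0")
  if (!is.finite(cfg$duration) || cfg$duration <= 0) bad("duration", "must be > 0")
  if (cfg$heart_rate < 30 || cfg$heart_rate > 200) {
    bad("heart_rate", "must lie in [30, 200] bpm")
  }
  if (cfg$powerline_freq < 40 || cfg$powerline_freq > 70) {
    bad("powerline_freq", "must lie in [40, 70] Hz")
  }
  if (cfg$drift_freq <= 0 || cfg$drift_freq >= 0.5) {
    bad("drift_freq", "must lie in (0, 0.5) Hz")
  }
  for (f in c("powerline_amp", "drift_amp", "white_sigma", "beat_jitter_sd")) {
    if (cfg[[f]] < 0) bad(f, "must be >= 0")
  }
  waves <- c("P", "Q", "R", "S", "T")
  for (f in c("wave_amplitudes", "wave_offsets", "wave_widths")) {
    if (!all(waves %in% names(cfg[[f]]))) bad(f, "must name all of P, Q, R, S, T")
  }
  if (any(cfg$wave_widths[waves] <= 0)) bad("wave_widths", "must be > 0")
  invisible(cfg)
}

#' Generate a clean synthetic MCG trace
#'
#' Builds a quasi-periodic waveform as a sum of five Gaussian bumps per beat
#' (P, Q, R, S, T) at fixed intra-beat offsets. Deterministic given the
#' config: beat-to-beat jitter, when enabled, is drawn from a generator
#' seeded by `cfg$seed`.
#'
#' @param cfg An [mcg_sim_config()].
#' @return An [mcg_signal()] of length `round(fs * duration)`.
#' @export
#' @examples
#' clean <- generate_clean_mcg(mcg_sim_config(duration = 4))
generate_clean_mcg <- function(cfg) {
  validate_sim_config(cfg)
  n <- round(cfg$fs * cfg$duration)
  t <- (seq_len(n) - 1L) / cfg$fs
  period <- 60 / cfg$heart_rate
  # R peaks at (i + 1/2) * period so a duration of k periods holds exactly k beats
  n_beats <- ceiling(cfg$duration / period) + 1L
  r_times <- (seq_len(n_beats) - 0.5) * period
  if (cfg$beat_jitter_sd > 0) {
    rng <- local_rng(cfg$seed + 1L)
    r_times <- r_times + rng(function() rnorm(n_beats, 0, cfg$beat_jitter_sd))
  }
  waves <- c("P", "Q", "R", "S", "T")
  x <- numeric(n)
  for (rt in r_times) {
    for (w in waves) {
      centre <- rt + cfg$wave_offsets[[w]]
      sdw <- cfg$wave_widths[[w]]
      # Gaussian support truncated at 5 sd; keeps the sum O(n_beats * n_window)
      lo <- max(1L, floor((centre - 5 * sdw) * cfg$fs) + 1L)
      hi <- min(n, ceiling((centre + 5 * sdw) * cfg$fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] +
        cfg$wave_amplitudes[[w]] * exp(-((t[idx] - centre)^2) / (2 * sdw^2))
    }
  }
  mcg_signal(x, fs = cfg$fs, label = "clean synthetic MCG")
}

#' Individual noise components for a simulation config
#'
#' Returns the three interference components that [corrupt_signal()] adds,
#' each as a column, so oracle tests can check them sample-wise.
#'
#' @param cfg An [mcg_sim_config()].
#' @param n Number of samples; defaults to `round(fs * duration)`.
#' @return A tibble with columns `time`, `powerline`, `drift`, `white`.
#' @export
noise_components <- function(cfg, n = round(cfg$fs * cfg$duration)) {
  validate_sim_config(cfg)
  t <- (seq_len(n) - 1L) / cfg$fs
  rng <- local_rng(cfg$seed + 2L)
  white <- if (cfg$white_sigma > 0) {
    rng(function() rnorm(n, 0, cfg$white_sigma))
  } else {
    numeric(n)
  }
  tibble::tibble(
    time = t,
    powerline = cfg$powerline_amp * sin(2 * pi * cfg$powerline_freq * t),
    drift = cfg$drift_amp * sin(2 * pi * cfg$drift_freq * t),
    white = white
  )
}

#' Corrupt a clean signal with structured interference
#'
#' Adds power-line pickup, baseline drift, and seeded white noise to a clean
#' trace. The sum of [noise_components()] equals `corrupt_signal(clean) -
#' clean` exactly.
#'
#' @param clean An [mcg_signal()]; its `fs` must match `cfg$fs`.
#' @param cfg An [mcg_sim_config()].
#' @return A corrupted [mcg_signal()].
#' @export
corrupt_signal <- function(clean, cfg) {
  validate_sim_config(cfg)
  if (abs(signal_fs(clean) - cfg$fs) > 1e-9 * cfg$fs) {
    abort("sampling rate of `clean` does not match `cfg$fs`.",
          class = "aovmd_config_error")
  }
  nc <- noise_components(cfg, n = nrow(clean))
  new_signal_like(clean,
    signal_values(clean) + (nc$powerline + nc$drift + nc$white),
    label = "corrupted synthetic MCG"
  )
}

#' Generate a mixture of cosine tones
#'
#' Fixture generator for decomposition tests: a plain sum of cosines.
#'
#' @param freqs Frequencies in Hz, each strictly below `fs / 2`.
#' @param amps Amplitudes, same length as `freqs`.
#' @param fs Sampling rate in Hz.
#' @param duration Duration in seconds.
#' @return An [mcg_signal()] (all zero when `freqs` is empty).
#' @export
generate_tone_mixture <- function(freqs, amps, fs, duration) {
  if (length(freqs) != length(amps)) {
    abort("`freqs` and `amps` must have equal length.", class = "aovmd_config_error")
  }
  if (length(freqs) && any(freqs >= fs / 2)) {
    abort("all frequencies must lie strictly below fs / 2 (Nyquist).",
          class = "aovmd_config_error")
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (i in seq_along(freqs)) {
    x <- x + amps[i] * cos(2 * pi * freqs[i] * t)
  }
  mcg_signal(x, fs = fs, label = "tone mixture")
}

# Run `expr_fn` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so package randomness never perturbs user code.
local_rng <- function(seed) {
  function(expr_fn) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
    expr_fn()
  }
}
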