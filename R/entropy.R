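#' Entropy configuration
#'
#' @param log_base Base of the logarithm: 10 (conventional "lg") or e.
#' @param normalize_max Divide by `log(N)` so the entropy lands in \[0, 1\].
#' @return A list of class `entropy_config`.
#' @export
entropy_config <- function(log_base = c("10", "e"), normalize_max = FALSE) {
  log_base <- match.arg(as.character(log_base[1]), c("10", "e"))
  structure(list(log_base = log_base, normalize_max = normalize_max),
            class = "entropy_config")
}

log_fn <- function(ecfg) {
  if (ecfg$log_base == "10") log10 else log
}

#' Hilbert envelope of a real signal
#'
#' Magnitude of the analytic signal `x + i * H(x)`, computed through the
#' FFT: positive frequencies doubled, negative frequencies zeroed.
#'
#' @param x Real numeric vector (length >= 2).
#' @return Nonnegative envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  x <- signal_values(x)
  if (length(x) < 2L) abort("`x` must have length >= 2.",
                            class = "aovmd_config_error")
  if (!all(is.finite(x))) abort("`x` must be finite.", class = "aovmd_config_error")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Envelope entropy of one mode
#'
#' Normalizes the Hilbert envelope into a probability distribution
#' `p_j = a_j / sum(a)` and returns its Shannon entropy
#' `-sum(p_j * log(p_j))`, with `0 * log(0) := 0`. Low values indicate a
#' sparse, pulse-like mode; broadband noise pushes the envelope toward
#' uniformity and the entropy toward `log(N)`.
#'
#' @param imf Real numeric vector (a mode, or any signal).
#' @param ecfg An [entropy_config()].
#' @return Nonnegative entropy value.
#' @export
envelope_entropy <- function(imf, ecfg = entropy_config()) {
  entropy_from_envelope(hilbert_envelope(imf), ecfg)
}

#' Shannon entropy of a nonnegative envelope
#'
#' The normalization and entropy step of [envelope_entropy()], exposed for
#' use with precomputed envelopes.
#'
#' @param a Nonnegative envelope values (not all zero).
#' @param ecfg An [entropy_config()].
#' @return Nonnegative entropy value.
#' @export
entropy_from_envelope <- function(a, ecfg = entropy_config()) {
  if (any(a < 0)) abort("envelope must be nonnegative.",
                        class = "aovmd_config_error")
  tot <- sum(a)
  if (tot == 0) abort("all-zero envelope: entropy undefined.",
                      class = "aovmd_config_error")
  p <- a / tot
  lg <- log_fn(ecfg)
  nz <- p > 0
  h <- -sum(p[nz] * lg(p[nz]))
  if (ecfg$normalize_max) h <- h / lg(length(p))
  h
}

#' Mean envelope entropy of a decomposition
#'
#' Arithmetic mean of the per-mode envelope entropies — the fitness the
#' optimizer minimizes when tuning (K, alpha).
#'
#' @param decomp An `mcg_vmd` object (or a numeric matrix, one mode per
#'   column).
#' @param ecfg An [entropy_config()].
#' @return Mean entropy value.
#' @export
mean_envelope_entropy <- function(decomp, ecfg = entropy_config()) {
  modes <- if (inherits(decomp, "mcg_vmd")) decomp$modes else as.matrix(decomp)
  if (ncol(modes) < 1L) abort("need at least one mode.", class = "aovmd_config_error")
  mean(apply(modes, 2L, envelope_entropy, ecfg = ecfg))
}

#' VMD mean-envelope-entropy objective
#'
#' Builds the objective the optimizer searches: a function of a position
#' `(K, alpha)` that decomposes `signal` with those parameters and returns
#' the mean envelope entropy. Decomposition failures return a large sentinel
#' so the candidate is rejected rather than crashing the search.
#'
#' @param signal An [mcg_signal()].
#' @param vparams A [vmd_params()] template; `K` and `alpha` are substituted
#'   per evaluation.
#' @param ecfg An [entropy_config()].
#' @param sentinel Fitness assigned when the decomposition fails.
#' @return A function `(position) -> fitness` suitable for [aoa_optimize()].
#' @export
vmd_mee_objective <- function(signal, vparams = vmd_params(),
                              ecfg = entropy_config(), sentinel = 1e6) {
  signal <- as_mcg_signal(signal)
  force(vparams); force(ecfg); force(sentinel)
  function(position) {
    k <- as.integer(round(position[1]))
    alpha <- position[2]
    p <- vparams
    p$K <- k
    p$alpha <- alpha
    tryCatch({
      d <- vmd_decompose(signal, p)
      mean_envelope_entropy(d, ecfg)
    }, error = function(e) {
      warn(sprintf("VMD failed at K=%d, alpha=%.4g: %s", k, alpha,
                   conditionMessage(e)))
      sentinel
    })
  }
}
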