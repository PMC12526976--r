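# Periodic orthogonal discrete wavelet transform.
#
# Analysis:  a[k] = sum_n h[n] x[(2k+n) mod N],  d[k] likewise with the
# quadrature mirror filter g[n] = (-1)^n h[L-1-n]. Synthesis is the adjoint.
# Perfect reconstruction for orthonormal filters is covered by tests.

wavelet_filters <- function(name) {
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
            -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    abort(sprintf("unknown wavelet '%s' (available: haar, db2, db4).", name),
          class = "aovmd_config_error")
  )
  l <- length(h)
  g <- rev(h) * (-1)^(seq_len(l) - 1)
  list(lo = h, hi = g, len = l)
}

dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2
  a <- numeric(half)
  d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)
  for (j in seq_len(filt$len)) {
    idx <- (base + j - 1) %% n + 1
    a <- a + filt$lo[j] * x[idx]
    d <- d + filt$hi[j] * x[idx]
  }
  list(approx = a, detail = d)
}

idwt_step <- function(a, d, filt, n) {
  x <- numeric(n)
  base <- 2 * (seq_along(a) - 1)
  for (j in seq_len(filt$len)) {
    idx <- (base + j - 1) %% n + 1
    acc <- filt$lo[j] * a + filt$hi[j] * d
    # scatter-add; indices within one j are distinct (stride 2, offset fixed)
    x[idx] <- x[idx] + acc
  }
  x
}

dwt_periodic <- function(x, wavelet = "db4", levels) {
  filt <- wavelet_filters(wavelet)
  n0 <- length(x)
  details <- vector("list", levels)
  pads <- integer(levels)
  cur <- x
  for (lev in seq_len(levels)) {
    if (length(cur) %% 2 == 1) {
      cur <- c(cur, cur[length(cur)])
      pads[lev] <- 1L
    }
    if (length(cur) < filt$len) {
      levels <- lev - 1L
      details <- details[seq_len(levels)]
      pads <- pads[seq_len(levels)]
      break
    }
    st <- dwt_step(cur, filt)
    details[[lev]] <- st$detail
    cur <- st$approx
  }
  list(approx = cur, details = details, pads = pads, n = n0,
       wavelet = wavelet, levels = length(details))
}

idwt_periodic <- function(dec) {
  filt <- wavelet_filters(dec$wavelet)
  cur <- dec$approx
  for (lev in rev(seq_len(dec$levels))) {
    n <- 2L * length(dec$details[[lev]])
    cur <- idwt_step(cur, dec$details[[lev]], filt, n)
    if (dec$pads[lev] == 1L) cur <- cur[-length(cur)]
  }
  cur[seq_len(dec$n)]
}

auto_wavelet_levels <- function(n) {
  max(3L, floor(log2(n)) - 6L)
}

#' Soft and hard threshold operators
#'
#' Soft: `sign(w) * max(|w| - lambda, 0)`; hard: `w * 1(|w| > lambda)`.
#'
#' @param w Coefficient vector.
#' @param lambda Threshold (>= 0).
#' @param mode `"soft"` or `"hard"`.
#' @return Thresholded coefficients.
#' @export
threshold_coefficients <- function(w, lambda, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  if (mode == "soft") {
    sign(w) * pmax(abs(w) - lambda, 0)
  } else {
    w * (abs(w) > lambda)
  }
}

#' Universal-threshold wavelet denoising
#'
#' Multilevel periodic DWT, universal threshold
#' `lambda = sigma_hat * sqrt(2 * log(N))` with the noise scale
#' `sigma_hat = median(|d1|) / 0.6745` estimated from the finest detail
#' level, soft or hard shrinkage of all detail coefficients, and inverse
#' transform cropped to the input length.
#'
#' @param x Numeric vector (or [mcg_signal()]).
#' @param wavelet Wavelet name (`"db4"`, `"db2"`, `"haar"`).
#' @param levels Decomposition depth; `NULL` picks
#'   `max(3, floor(log2(N)) - 6)`.
#' @param mode Threshold operator, `"soft"` (default) or `"hard"`.
#' @return Denoised numeric vector, same length as the input.
#' @export
wavelet_shrink <- function(x, wavelet = "db4", levels = NULL,
                           mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  vals <- signal_values(x)
  n <- length(vals)
  if (n < 2L) abort("input too short for wavelet denoising.",
                    class = "aovmd_config_error")
  levels <- levels %||% auto_wavelet_levels(n)
  dec <- dwt_periodic(vals, wavelet, levels)
  if (dec$levels == 0L) return(vals)
  sigma <- median(abs(dec$details[[1]])) / 0.6745
  lambda <- sigma * sqrt(2 * log(n))
  dec$details <- lapply(dec$details, threshold_coefficients,
                        lambda = lambda, mode = mode)
  idwt_periodic(dec)
}
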