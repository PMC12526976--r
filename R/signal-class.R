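#' Uniformly sampled signal
#'
#' The basic carrier for raw and denoised magnetocardiography (MCG) traces:
#' a tibble with columns `time` (seconds) and `value` (amplitude, arbitrary
#' units standing in for picotesla), carrying the sampling rate `fs` as an
#' attribute. All user-facing functions in the package accept and return
#' this shape so calls chain with the pipe.
#'
#' @param value Numeric vector of samples (length >= 2, all finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param label Optional free-text label.
#'
#' @return A tibble of class `mcg_signal` with columns `time` and `value`.
#' @export
#' @examples
#' s <- mcg_signal(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs = 1000)
#' signal_fs(s)
mcg_signal <- function(value, fs, label = "") {
  value <- as.numeric(value)
  if (length(value) < 2L) {
    abort("`value` must contain at least 2 samples.", class = "aovmd_config_error")
  }
  if (!all(is.finite(value))) {
    abort("`value` must be finite throughout.", class = "aovmd_config_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).", class = "aovmd_config_error")
  }
  out <- tibble::tibble(
    time = (seq_along(value) - 1L) / fs,
    value = value
  )
  structure(out,
    fs = fs, label = as.character(label)[1],
    class = c("mcg_signal", class(tibble::tibble()))
  )
}

#' Coerce a data frame to an `mcg_signal`
#'
#' Two-column data frames (`time`, `value` — names flexible, first column is
#' taken as time) have `fs` inferred from the median time step, which must be
#' uniform to 1e-6 relative. One-column data frames require `fs`.
#'
#' @param x A data frame, or a bare numeric vector.
#' @param fs Sampling rate override in Hz (required for one-column input).
#' @param label Optional label.
#' @return An [mcg_signal()].
#' @export
as_mcg_signal <- function(x, fs = NULL, label = "") {
  if (inherits(x, "mcg_signal") && is.null(fs)) return(x)
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(fs)) abort("`fs` is required for a bare sample vector.",
                           class = "aovmd_config_error")
    return(mcg_signal(x, fs = fs, label = label))
  }
  x <- as.data.frame(x)
  if (ncol(x) == 1L) {
    if (is.null(fs)) {
      abort("one-column input requires an explicit `fs`.", class = "aovmd_config_error")
    }
    return(mcg_signal(x[[1]], fs = fs, label = label))
  }
  tcol <- x[[1]]
  dt <- diff(tcol)
  if (any(dt <= 0)) abort("time column must be strictly increasing.",
                          class = "aovmd_io_error")
  dt_med <- median(dt)
  if (max(abs(dt - dt_med)) > 1e-6 * dt_med) {
    abort("time grid is not uniform (relative tolerance 1e-6).",
          class = "aovmd_io_error")
  }
  mcg_signal(x[[2]], fs = fs %||% (1 / dt_med), label = label)
}

#' @export
print.mcg_signal <- function(x, ...) {
  cat(sprintf(
    "<mcg_signal> %d samples @ %g Hz (%.3f s)%s\n",
    nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs"),
    if (nzchar(attr(x, "label") %||% "")) paste0("  [", attr(x, "label"), "]") else ""
  ))
  NextMethod()
}

#' Sampling rate of a signal
#' @param x An [mcg_signal()].
#' @return Sampling rate in Hz.
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("`x` carries no sampling rate; use as_mcg_signal().")
  fs
}

#' Sample values of a signal
#' @param x An [mcg_signal()] or data frame with a `value` column.
#' @return Numeric vector of samples.
#' @export
signal_values <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(x[["value"]])
}

# Rebuild an mcg_signal from new samples, inheriting fs/label from a template.
new_signal_like <- function(template, value, label = NULL) {
  mcg_signal(value, fs = signal_fs(template),
             label = label %||% attr(template, "label") %||% "")
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b)) abort("signals differ in length.", class = "aovmd_config_error")
  if (abs(signal_fs(a) - signal_fs(b)) > 1e-9 * signal_fs(a)) {
    abort("signals differ in sampling rate.", class = "aovmd_config_error")
  }
  invisible(TRUE)
}
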