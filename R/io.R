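#' Read a signal from CSV
#'
#' Accepts one-column (`value`) or two-column (`time_s,value`) files, with
#' or without a header. Two-column files have the sampling rate inferred
#' from the time column, which must be uniform to 1e-6 relative; one-column
#' files require `fs_override`.
#'
#' @param path CSV file path.
#' @param fs_override Sampling rate in Hz (required for one-column files,
#'   overrides the inferred rate otherwise).
#' @param label Optional label for the signal.
#' @return An [mcg_signal()].
#' @export
read_signal_csv <- function(path, fs_override = NULL, label = "") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path),
                                class = "aovmd_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty file.", class = "aovmd_io_error")
  first <- strsplit(lines[1], ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  rows <- strsplit(body, ",")
  ncols <- length(rows[[1]])
  if (!ncols %in% c(1L, 2L)) {
    abort("expected 1 or 2 columns (value, or time,value).",
          class = "aovmd_io_error")
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncols)
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(vals) != ncols || any(is.na(vals))) {
      abort(sprintf("non-numeric row at line %d of %s", i + offset, path),
            class = "aovmd_io_error")
    }
    mat[i, ] <- vals
  }
  as_mcg_signal(as.data.frame(mat), fs = fs_override, label = label)
}

#' Write a signal to CSV with a JSON sidecar
#'
#' The CSV holds `time_s,value`; the sidecar (written when `sidecar` is
#' given) records the full generating configuration and seed so any run is
#' reproducible from its artifacts alone.
#'
#' @param signal An [mcg_signal()].
#' @param path CSV output path.
#' @param sidecar Optional named list (e.g. an [mcg_sim_config()]) written
#'   to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path, sidecar = NULL) {
  signal <- as_mcg_signal(signal)
  utils::write.csv(
    data.frame(time_s = signal$time, value = signal$value),
    path, row.names = FALSE
  )
  if (!is.null(sidecar)) {
    jsonlite::write_json(
      c(unclass(sidecar), list(fs = signal_fs(signal), n = nrow(signal))),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}
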