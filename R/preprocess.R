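#' Band-pass filter specification
#'
#' Zero-phase Butterworth band-pass, applied forward and backward. Defaults
#' match the clinical pre-processing band of 0.53-60 Hz.
#'
#' @param low_cut lower edge in Hz.
#' @param high_cut upper edge in Hz; must stay below the record's Nyquist rate.
#' @param order Butterworth prototype order (per edge).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.53, high_cut = 60, order = 4L) {
  if (!(low_cut > 0 && high_cut > low_cut))
    stop_hos("need 0 < low_cut < high_cut")
  if (order < 1) stop_hos("filter order must be >= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = as.integer(order)),
            class = "filter_spec")
}

#' Zero-phase band-pass filtering
#'
#' Filters the record forward and backward (zero net phase shift) with a
#' Butterworth band-pass. Reflective padding of three filter lengths at each
#' end suppresses startup transients on short records.
#'
#' @param record an [eeg_record].
#' @param spec a [filter_spec].
#' @return the filtered [eeg_record] (same length).
#' @export
bandpass_zero_phase <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "eeg_record"), inherits(spec, "filter_spec"))
  nyq <- record$fs / 2
  if (spec$high_cut >= nyq)
    stop_hos(sprintf("high_cut (%.2f Hz) must be below the Nyquist rate (%.2f Hz)",
                     spec$high_cut, nyq))
  bf <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  x <- record$samples - mean(record$samples)  # DC lies below the pass-band
  n <- length(x)
  pad <- min(3L * (length(bf$b) - 1L), n - 1L)
  if (pad > 0L) {
    # odd reflection about the end points (keeps the extension continuous)
    head_ext <- 2 * x[1L] - x[(pad + 1L):2L]
    tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(head_ext, x, tail_ext)
  } else xp <- x
  y <- signal::filtfilt(bf, xp)
  if (pad > 0L) y <- y[(pad + 1L):(pad + n)]
  rec <- record
  rec$samples <- y
  rec
}

#' Partition a record into equal non-overlapping windows
#'
#' Windows are contiguous and ordered; trailing remainder samples (when the
#' record length is not a multiple of `n_windows`) are dropped.
#'
#' @param record an [eeg_record].
#' @param n_windows number of windows.
#' @return list of `eeg_window` objects, each with fields `samples`,
#'   `parent_record`, `index`, `fs`.
#' @export
window_record <- function(record, n_windows = 16L) {
  stopifnot(inherits(record, "eeg_record"))
  n_windows <- as.integer(n_windows)
  if (n_windows <= 0L) stop_hos("n_windows must be positive")
  n <- length(record$samples)
  wlen <- n %/% n_windows
  if (wlen < 1L) stop_hos("record shorter than n_windows")
  lapply(seq_len(n_windows), function(i) {
    idx <- ((i - 1L) * wlen + 1L):(i * wlen)
    structure(list(samples = record$samples[idx],
                   parent_record = record$record_id, index = i,
                   fs = record$fs),
              class = "eeg_window")
  })
}

#' @export
print.eeg_window <- function(x, ...) {
  cat(sprintf("<eeg_window> %s[%d]: %d samples @ %.2f Hz\n",
              x$parent_record, x$index, length(x$samples), x$fs))
  invisible(x)
}
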