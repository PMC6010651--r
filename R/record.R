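#' Single-channel EEG record
#'
#' Lightweight container for one single-channel EEG segment: a numeric sample
#' vector plus sampling metadata. The Bonn-style corpus this package targets
#' stores one such record per plain-text file (one integer sample per line,
#' 173.61 Hz, about 23.6 s, i.e. ~4096 samples).
#'
#' @param samples numeric vector of amplitudes (arbitrary microvolt-scaled
#'   units); must be finite and non-empty.
#' @param fs sampling rate in Hz.
#' @param set_id set label (Bonn sets are "A".."E"; synthetic labels allowed).
#' @param record_id identifier for the record within its set.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs = 173.61, set_id = NA_character_,
                       record_id = NA_character_) {
  samples <- as.double(samples)
  if (length(samples) == 0L) stop_hos("an EEG record needs at least one sample")
  if (!all(is.finite(samples))) stop_hos("EEG samples must all be finite")
  if (!is.numeric(fs) || fs <= 0) stop_hos("sampling rate 'fs' must be > 0")
  structure(
    list(samples = samples, fs = fs, set_id = as.character(set_id),
         record_id = as.character(record_id)),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s/%s: %d samples @ %.2f Hz (%.1f s)\n",
              x$set_id, x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$samples)

#' Read a Bonn-format EEG record
#'
#' Bonn-format files carry one numeric sample per line, no header. The reader
#' is length-agnostic (the published corpus mixes 4096- and 4097-line files).
#'
#' @param path path to a one-column ASCII file.
#' @param fs sampling rate to attach (default 173.61 Hz, the corpus rate).
#' @param set_id,record_id metadata to attach; by default derived from the path.
#' @return an [eeg_record].
#' @export
read_bonn_record <- function(path, fs = 173.61, set_id = NA_character_,
                             record_id = NULL) {
  if (!file.exists(path)) stop_hos("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_hos("empty record file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop_hos(sprintf("parse error in '%s': non-numeric value on line %d (\"%s\")",
                     path, bad, lines[bad]))
  }
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  eeg_record(vals, fs = fs, set_id = set_id, record_id = record_id)
}

#' Write an EEG record in Bonn format
#'
#' Writes one sample per line. Samples are rounded to integers to match the
#' corpus dialect.
#'
#' @param record an [eeg_record].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bonn_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  ok <- try(writeLines(format(round(record$samples), scientific = FALSE,
                              trim = TRUE), path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_hos("failed to write '", path, "': ", attr(ok, "condition")$message)
  invisible(path)
}
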