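#' Specification of a quadratically phase-coupled test signal
#'
#' Describes a three-component sinusoidal signal at frequencies `f1`, `f2` and
#' `f1 + f2`. When `coupled = TRUE` the third component's phase is the sum of
#' the first two (quadratic phase coupling, QPC), which produces a bicoherence
#' peak at `(f1, f2)`; when `FALSE` the third phase is an independent uniform
#' draw, which destroys the bispectral peak while leaving the power spectrum
#' unchanged.
#'
#' Phases are redrawn independently every `block_len` samples so that
#' segment-averaged bispectral estimators see phase diversity across segments
#' (a single global phase triple would make the uncoupled case look coupled to
#' any single-segment estimate).
#'
#' @param f1,f2 component frequencies in Hz; `0 < f1 < f2`, `f1 + f2 < fs/2`.
#' @param amplitudes length-3 numeric amplitudes for the components at
#'   `f1`, `f2`, `f1 + f2`.
#' @param coupled logical; quadratic phase coupling on or off.
#' @param noise_sd standard deviation of additive white Gaussian noise.
#' @param fs sampling rate in Hz.
#' @param n_samples record length in samples.
#' @param seed integer seed; identical spec + seed is bit-reproducible.
#' @param block_len phase-renewal block length in samples.
#' @return an object of class `qpc_spec`.
#' @export
qpc_spec <- function(f1, f2, amplitudes = c(1, 1, 1), coupled = TRUE,
                     noise_sd = 0, fs = 173.61, n_samples = 4096,
                     seed = NULL, block_len = 64L) {
  if (!(f1 > 0 && f2 > f1)) stop_hos("need 0 < f1 < f2")
  if (f1 + f2 >= fs / 2)
    stop_hos(sprintf("f1 + f2 = %.2f Hz is at or above the Nyquist rate %.2f Hz",
                     f1 + f2, fs / 2))
  if (length(amplitudes) != 3L || any(!is.finite(amplitudes)))
    stop_hos("'amplitudes' must be three finite numbers")
  if (n_samples <= 0) stop_hos("n_samples must be positive")
  structure(
    list(f1 = f1, f2 = f2, amplitudes = as.double(amplitudes),
         coupled = isTRUE(coupled), noise_sd = noise_sd, fs = fs,
         n_samples = as.integer(n_samples), seed = seed,
         block_len = as.integer(block_len)),
    class = "qpc_spec"
  )
}

# Shared sample generator; `strength` in [0,1] splits the third component's
# amplitude between a phase-coupled part and an independent-phase part.
qpc_samples <- function(spec, strength) {
  n <- spec$n_samples
  L <- min(spec$block_len, n)
  a <- spec$amplitudes
  w <- 2 * pi * c(spec$f1, spec$f2, spec$f1 + spec$f2)
  x <- numeric(n)
  starts <- seq.int(1L, n, by = L)
  for (s in starts) {
    idx <- s:min(s + L - 1L, n)
    t <- (seq_along(idx) - 1L) / spec$fs
    ph <- stats::runif(3L, 0, 2 * pi)  # phi1, phi2, independent phi3
    x[idx] <- a[1L] * cos(w[1L] * t + ph[1L]) +
      a[2L] * cos(w[2L] * t + ph[2L]) +
      a[3L] * (strength * cos(w[3L] * t + ph[1L] + ph[2L]) +
                 (1 - strength) * cos(w[3L] * t + ph[3L]))
  }
  if (spec$noise_sd > 0) x <- x + stats::rnorm(n, sd = spec$noise_sd)
  x
}

#' Generate a quadratically phase-coupled (or uncoupled) signal
#'
#' @param spec a [qpc_spec].
#' @return an [eeg_record] of `spec$n_samples` samples.
#' @export
gen_qpc_signal <- function(spec) {
  stopifnot(inherits(spec, "qpc_spec"))
  x <- with_seed(spec$seed, qpc_samples(spec, strength = as.numeric(spec$coupled)))
  eeg_record(x, fs = spec$fs, set_id = "synthetic",
             record_id = if (spec$coupled) "qpc" else "qpc-uncoupled")
}

#' Generate a white Gaussian record
#'
#' Zero-mean unit-variance white Gaussian samples; the null case for the
#' Hinich Gaussianity test.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return an [eeg_record].
#' @export
gen_gaussian_record <- function(n, fs = 173.61, seed = NULL) {
  if (n <= 0) stop_hos("n must be positive")
  x <- with_seed(seed, stats::rnorm(n))
  eeg_record(x, fs = fs, set_id = "synthetic", record_id = "gauss")
}

#' Recipe for one synthetic Bonn-like set
#'
#' Stands in for one of the corpus sets A-E: a class label plus the band pair
#' where quadratic phase coupling is placed and how strongly. Coupling
#' frequencies are the first bi-frequency grid bins falling inside each band
#' (at the pipeline's 64-point segment grid), so downstream band-region
#' features see the coupling where the recipe puts it.
#'
#' @param class_label one of `"healthy"`, `"interictal"`, `"ictal"` (free-form
#'   labels are accepted for non-default designs).
#' @param qpc_band_pair character pair from `delta`, `theta`, `alpha`, `beta`.
#' @param coupling_strength in `[0, 1]`; 0 means independent phases.
#' @param records_per_class records to emit for this set.
#' @param noise_sd additive noise standard deviation.
#' @return an object of class `class_recipe`.
#' @export
class_recipe <- function(class_label, qpc_band_pair = c("theta", "alpha"),
                         coupling_strength = 1, records_per_class = 100L,
                         noise_sd = 0.25) {
  bands <- c("delta", "theta", "alpha", "beta")
  qpc_band_pair <- as.character(qpc_band_pair)
  if (length(qpc_band_pair) != 2L || !all(qpc_band_pair %in% bands))
    stop_hos("qpc_band_pair must be two of: ", paste(bands, collapse = ", "))
  if (coupling_strength < 0 || coupling_strength > 1)
    stop_hos("coupling_strength must lie in [0, 1]")
  structure(
    list(class_label = as.character(class_label), qpc_band_pair = qpc_band_pair,
         coupling_strength = coupling_strength,
         records_per_class = as.integer(records_per_class),
         noise_sd = noise_sd),
    class = "class_recipe"
  )
}

# Representative bin-aligned frequency pair for a band pair, on the fs/64 grid.
band_pair_freqs <- function(pair, fs = 173.61, nfft = 64L,
                            scheme = band_scheme()) {
  df <- fs / nfft
  bins <- df * seq_len(nfft / 2 - 1)
  in_band <- function(b) bins[bins >= scheme$low[b] & bins < scheme$high[b]]
  if (pair[1L] == pair[2L]) {
    f <- in_band(pair[1L])
    if (length(f) < 2L)
      stop_hos("band '", pair[1L], "' holds fewer than two grid bins at this ",
               "resolution; pick a distinct band pair")
    f <- f[1:2]
  } else {
    f <- sort(c(in_band(pair[1L])[1L], in_band(pair[2L])[1L]))
  }
  if (anyNA(f)) stop_hos("no grid bin inside band pair ", paste(pair, collapse = "-"))
  if (sum(f) >= fs / 2) stop_hos("band pair sum frequency exceeds Nyquist")
  f
}

#' Default recipes emulating the five-set corpus layout
#'
#' Sets A and B are healthy (no phase coupling), C and D interictal
#' (delta-theta coupling of increasing strength) and E ictal (full-strength
#' alpha-beta coupling).
#'
#' @param records_per_class records per set.
#' @return named list of [class_recipe]s for sets A-E.
#' @export
default_bonn_recipes <- function(records_per_class = 100L) {
  list(
    A = class_recipe("healthy", c("theta", "alpha"), 0, records_per_class),
    B = class_recipe("healthy", c("alpha", "beta"), 0, records_per_class),
    C = class_recipe("interictal", c("delta", "theta"), 0.5, records_per_class),
    D = class_recipe("interictal", c("delta", "theta"), 0.8, records_per_class),
    E = class_recipe("ictal", c("alpha", "beta"), 1, records_per_class)
  )
}

#' Write a synthetic Bonn-like dataset
#'
#' Emits one-column ASCII files (one integer sample per line) in per-set
#' subdirectories plus a `manifest.csv` mapping each file to its set and class.
#' Records are 4096 samples at 173.61 Hz by default (173.61 Hz x 23.6 s ~ 4096)
#' and are amplitude-scaled into roughly the +/-2000 integer range of the
#' clinical corpus before rounding.
#'
#' @param recipes named list of [class_recipe]s (names are set ids).
#' @param out_dir output directory (created if needed).
#' @param n_samples samples per record.
#' @param fs sampling rate in Hz.
#' @param seed master seed; per-record seeds are derived deterministically.
#' @param gain amplitude scale applied before integer rounding.
#' @return data.frame manifest with columns `file`, `set`, `class`, invisibly
#'   also written to `out_dir/manifest.csv`.
#' @export
gen_bonn_like_dataset <- function(recipes = default_bonn_recipes(),
                                  out_dir, n_samples = 4096L, fs = 173.61,
                                  seed = 1L, gain = 400) {
  if (is.null(names(recipes)) || any(!nzchar(names(recipes))))
    stop_hos("'recipes' must be a named list (set ids as names)")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_hos("cannot create output directory: ", out_dir)
  rows <- list()
  for (set_id in names(recipes)) {
    rc <- recipes[[set_id]]
    stopifnot(inherits(rc, "class_recipe"))
    f12 <- band_pair_freqs(rc$qpc_band_pair, fs = fs)
    set_dir <- file.path(out_dir, set_id)
    dir.create(set_dir, showWarnings = FALSE)
    for (i in seq_len(rc$records_per_class)) {
      rseed <- derive_seed(seed, paste0(set_id, "-", i))
      spec <- qpc_spec(f12[1L], f12[2L], coupled = TRUE,
                       noise_sd = rc$noise_sd, fs = fs,
                       n_samples = n_samples, seed = rseed)
      x <- with_seed(rseed, qpc_samples(spec, strength = rc$coupling_strength))
      rec <- eeg_record(x * gain, fs = fs, set_id = set_id,
                        record_id = sprintf("%s%03d", set_id, i))
      path <- file.path(set_dir, sprintf("%s%03d.txt", set_id, i))
      write_bonn_record(rec, path)
      rows[[length(rows) + 1L]] <-
        data.frame(file = file.path(set_id, basename(path)), set = set_id,
                   class = rc$class_label, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
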