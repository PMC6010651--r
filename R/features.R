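#' Clinical EEG band scheme
#'
#' Four contiguous half-open bands `[low, high)` in Hz used to partition the
#' principal domain of the bi-frequency plane. Defaults are the standard
#' clinical bands, with the delta floor at the 0.53 Hz pre-processing edge:
#' delta `[0.53, 4)`, theta `[4, 8)`, alpha `[8, 13)`, beta `[13, 30)`.
#'
#' @param edges numeric vector of 5 ascending edges.
#' @param names band names (length 4).
#' @return object of class `band_scheme` with `low`, `high` named vectors.
#' @export
band_scheme <- function(edges = c(0.53, 4, 8, 13, 30),
                        names = c("delta", "theta", "alpha", "beta")) {
  if (length(edges) != length(names) + 1L || is.unsorted(edges, strictly = TRUE))
    stop_hos("band edges must be strictly ascending, one more than the names")
  structure(list(low = stats::setNames(edges[-length(edges)], names),
                 high = stats::setNames(edges[-1L], names),
                 names = names),
            class = "band_scheme")
}

band_pairs <- function(scheme) {
  nm <- scheme$names
  out <- list()
  for (i in seq_along(nm)) for (j in i:length(nm)) {
    out[[length(out) + 1L]] <- c(nm[i], nm[j])
  }
  out  # 10 unordered pairs (with repetition) for 4 bands
}

#' Band-pair summation regions on the principal domain
#'
#' Assigns every principal-domain cell to the unordered pair of bands its
#' centre frequencies fall in (half-open intervals; cells outside all bands
#' belong to no pair region), yielding the 10 pair regions, plus the whole
#' principal domain as an 11th region.
#'
#' @param scheme a [band_scheme].
#' @param domain a [principal_domain].
#' @return object of class `region_set`: a named list of logical masks
#'   (`delta.delta`, ..., `beta.beta`, `whole`) plus the `grid`.
#' @export
build_regions <- function(scheme = band_scheme(), domain) {
  stopifnot(inherits(scheme, "band_scheme"), inherits(domain, "principal_domain"))
  grid <- domain$grid
  if (max(scheme$high) > grid$fs / 2)
    stop_hos("band top edge exceeds the grid Nyquist rate")
  f <- grid$freq_axis
  band_of <- function(fr) {
    b <- rep(NA_character_, length(fr))
    for (nm in scheme$names) b[fr >= scheme$low[nm] & fr < scheme$high[nm]] <- nm
    b
  }
  bf <- band_of(f)
  m <- length(f)
  regions <- list()
  for (p in band_pairs(scheme)) {
    mask <- outer(seq_len(m), seq_len(m), function(i, j) {
      bi <- bf[i]; bj <- bf[j]
      !is.na(bi) & !is.na(bj) &
        ((bi == p[1L] & bj == p[2L]) | (bi == p[2L] & bj == p[1L]))
    })
    regions[[paste(p, collapse = ".")]] <- mask & domain$mask
  }
  regions$whole <- domain$mask
  structure(list(regions = regions, grid = grid, scheme = scheme),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions on nfft=%d grid\n",
              length(x$regions), x$grid$nfft))
  for (nm in names(x$regions))
    cat(sprintf("  %-12s %4d cells\n", nm, sum(x$regions[[nm]])))
  invisible(x)
}

#' Canonical names of the 47 features
#'
#' For each of the 11 regions: sum of bispectrum magnitudes `sumBis`, sum of
#' squared bispectrum magnitudes `sumBis2`, sum of bicoherence magnitudes
#' `sumBic`, sum of squared bicoherence magnitudes `sumBic2`; then the Hinich
#' triple `chi2`, `lambda`, `pfa`. 11 x 4 + 3 = 47.
#'
#' @param scheme a [band_scheme].
#' @return character vector of length 47.
#' @export
feature_names <- function(scheme = band_scheme()) {
  regs <- c(vapply(band_pairs(scheme), paste, "", collapse = "."), "whole")
  c(as.vector(t(outer(regs, c("sumBis", "sumBis2", "sumBic", "sumBic2"),
                      function(r, q) paste(q, r, sep = "_")))),
    "chi2", "lambda", "pfa")
}

#' Assemble the 47-dimensional feature vector
#'
#' Region-wise sums of bispectrum and bicoherence magnitudes (and their
#' squares) over the 10 band-pair regions and the whole principal domain,
#' followed by the Hinich chi-squared, lambda and Pfa.
#'
#' @param bis a `bispectrum` estimate.
#' @param bic a `bicoherence` estimate on the same grid.
#' @param hin a `hinich_test` result.
#' @param regions a [build_regions()] region set on the same grid.
#' @return named numeric vector of length 47.
#' @export
extract_features <- function(bis, bic, hin, regions) {
  stopifnot(inherits(bis, "bispectrum"), inherits(bic, "bicoherence"),
            inherits(hin, "hinich_test"), inherits(regions, "region_set"))
  if (bis$grid$nfft != regions$grid$nfft || bic$grid$nfft != regions$grid$nfft)
    stop_hos("bispectrum, bicoherence and regions must share one grid")
  bmag <- Mod(bis$values)
  cmag <- bic$values
  vals <- unlist(lapply(regions$regions, function(mask) {
    c(sum(bmag[mask]), sum(bmag[mask]^2), sum(cmag[mask]), sum(cmag[mask]^2))
  }), use.names = FALSE)
  out <- c(vals, hin$chi2_gauss, hin$lambda_lin, hin$pfa)
  stats::setNames(out, feature_names(regions$scheme))
}

#' Per-window HOS feature extraction
#'
#' Computes the full 47-feature vector for one analysis window by subdividing
#' it into overlapping sub-segments (so the bicoherence normalization and the
#' Hinich statistics have segments to average over), estimating the direct
#' bispectrum and bicoherence, and summing over the band regions.
#'
#' @param window an `eeg_window` or numeric vector.
#' @param fs sampling rate in Hz (taken from the window when available).
#' @param seg_len sub-segment length in samples.
#' @param overlap fractional overlap between consecutive sub-segments.
#' @param regions optional precomputed [build_regions()] set (must match
#'   `nfft = seg_len`); built on the fly otherwise.
#' @return named numeric feature vector of length 47.
#' @export
window_features <- function(window, fs = NULL, seg_len = 64L, overlap = 0.75,
                            regions = NULL) {
  fs <- fs %||% infer_fs(list(window))
  x <- if (inherits(window, "eeg_window")) window$samples else as.double(window)
  segs <- subdivide(x, seg_len, overlap)
  bis <- bispectrum_direct(segs, nfft = seg_len, fs = fs)
  bic <- bicoherence(segs, nfft = seg_len, fs = fs)
  hin <- hinich_from_bicoherence(bic)
  if (is.null(regions))
    regions <- build_regions(band_scheme(), principal_domain(bis$grid))
  extract_features(bis, bic, hin, regions)
}

# Overlapping sub-segments of x as a matrix (columns = segments).
subdivide <- function(x, seg_len, overlap) {
  seg_len <- as.integer(seg_len)
  if (seg_len > length(x)) stop_hos("seg_len exceeds the window length")
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq.int(1L, length(x) - seg_len + 1L, by = step)
  vapply(starts, function(s) x[s:(s + seg_len - 1L)], numeric(seg_len))
}

#' Fit a z-score normalizer on training features
#'
#' Stores the per-feature mean and standard deviation of the training matrix;
#' applying the normalizer computes `(x - m) / s`. Zero-variance features are
#' flagged, dropped from the output and reported with a warning, so they never
#' reach feature selection.
#'
#' @param train_features numeric matrix (rows = instances, columns = features)
#'   or list of feature vectors.
#' @return object of class `normalizer` with `mean`, `sd`, `keep`.
#' @export
fit_normalizer <- function(train_features) {
  X <- if (is.matrix(train_features)) train_features else do.call(rbind, train_features)
  if (nrow(X) < 2L) stop_hos("need at least two training vectors")
  m <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  keep <- s > 0
  if (any(!keep))
    warning(sprintf("dropping %d zero-variance feature(s): %s", sum(!keep),
                    paste(colnames(X)[!keep], collapse = ", ")),
            call. = FALSE)
  structure(list(mean = m, sd = s, keep = keep, n_train = nrow(X)),
            class = "normalizer")
}

#' Apply a fitted normalizer
#'
#' @param norm a [fit_normalizer()] object.
#' @param x feature matrix or single feature vector.
#' @return z-scored matrix restricted to the retained (non-constant) features.
#' @export
apply_normalizer <- function(norm, x) {
  stopifnot(inherits(norm, "normalizer"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L,
                                       dimnames = list(NULL, names(x)))
  if (ncol(X) != length(norm$mean)) stop_hos("feature dimensionality mismatch")
  Z <- sweep(sweep(X, 2L, norm$mean), 2L, ifelse(norm$keep, norm$sd, 1), "/")
  Z[, norm$keep, drop = FALSE]
}

#' @export
print.normalizer <- function(x, ...) {
  cat(sprintf("<normalizer> fitted on %d instances; %d/%d features retained\n",
              x$n_train, sum(x$keep), length(x$keep)))
  invisible(x)
}

#' @export
predict.normalizer <- function(object, newdata, ...) apply_normalizer(object, newdata)
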