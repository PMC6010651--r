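#' Bi-frequency grid
#'
#' One-sided frequency axis shared by both axes of the bi-frequency plane,
#' with resolution `fs/nfft`.
#'
#' @param nfft transform length (even).
#' @param fs sampling rate in Hz.
#' @return object of class `bifrequency_grid` with fields `nfft`, `fs`,
#'   `freq_axis` (Hz values `0, fs/nfft, ..., fs/2`).
#' @export
bifrequency_grid <- function(nfft, fs) {
  nfft <- as.integer(nfft)
  if (nfft < 4L || nfft %% 2L != 0L) stop_hos("nfft must be an even integer >= 4")
  if (fs <= 0) stop_hos("fs must be positive")
  structure(list(nfft = nfft, fs = fs,
                 freq_axis = fs * (0:(nfft %/% 2L)) / nfft),
            class = "bifrequency_grid")
}

# Mean-removed, zero-padded FFTs of all segments: nfft x K complex matrix.
segment_ffts <- function(segs, nfft) {
  wlen <- nrow(segs)
  if (nfft < wlen) stop_hos("nfft must be >= segment length")
  segs <- sweep(segs, 2L, colMeans(segs))
  if (nfft > wlen) segs <- rbind(segs, matrix(0, nfft - wlen, ncol(segs)))
  stats::mvfft(segs)
}

# Index (into the full FFT vector) of the f1+f2 bin for each one-sided cell.
sum_index <- function(nfft) {
  m <- nfft %/% 2L + 1L
  a <- 0:(m - 1L)
  outer(a, a, function(i, j) ((i + j) %% nfft) + 1L)
}

#' Direct-FFT bispectrum estimate
#'
#' For each mean-removed segment with discrete spectrum `X`, accumulates the
#' triple product `X(f1) X(f2) conj(X(f1+f2))` on the one-sided bi-frequency
#' grid and averages over segments.
#'
#' @param windows segments to average: a list of windows/numeric vectors or a
#'   numeric matrix with segments in columns, all of one length.
#' @param nfft transform length; defaults to the segment length.
#' @param fs sampling rate in Hz (taken from window objects when available).
#' @return object of class `bispectrum`: complex `values` matrix (rows `f1`,
#'   columns `f2`), `grid`, `method`, `n_segments`.
#' @export
bispectrum_direct <- function(windows, nfft = NULL, fs = NULL) {
  fs <- fs %||% infer_fs(windows)
  segs <- as_segment_matrix(windows)
  if (ncol(segs) < 1L) stop_hos("need at least one segment")
  nfft <- as.integer(nfft %||% nrow(segs))
  X <- segment_ffts(segs, nfft)
  m <- nfft %/% 2L + 1L
  idx <- sum_index(nfft)
  B <- matrix(0 + 0i, m, m)
  for (k in seq_len(ncol(X))) {
    Xh <- X[1:m, k]
    B <- B + outer(Xh, Xh) * Conj(matrix(X[idx, k], m, m))
  }
  B <- B / ncol(X)
  new_bispectrum(B, bifrequency_grid(nfft, fs), "direct", ncol(X))
}

#' Indirect (third-order cumulant) bispectrum estimate
#'
#' Estimates third-order cumulants `c3(m, n)` up to `max_lag` per mean-removed
#' segment (biased normalization), averages them over segments, applies a
#' Parzen lag-window taper `w(m) w(n) w(m - n)` and transforms to the
#' bi-frequency plane.
#'
#' @inheritParams bispectrum_direct
#' @param max_lag maximum cumulant lag; must be below the segment length.
#' @return object of class `bispectrum` with `method = "indirect"`.
#' @export
bispectrum_indirect <- function(windows, max_lag = NULL, nfft = NULL, fs = NULL) {
  fs <- fs %||% infer_fs(windows)
  segs <- as_segment_matrix(windows)
  wlen <- nrow(segs)
  max_lag <- as.integer(max_lag %||% min(64L, wlen %/% 2L))
  if (max_lag >= wlen) stop_hos("max_lag must be below the segment length")
  if (max_lag < 1L) stop_hos("max_lag must be >= 1")
  nfft <- as.integer(nfft %||% max(wlen, 2L * max_lag + 2L))
  if (nfft < 2L * max_lag + 1L) stop_hos("nfft too small for max_lag")
  L <- max_lag
  lags <- -L:L
  c3 <- matrix(0, 2L * L + 1L, 2L * L + 1L)
  for (k in seq_len(ncol(segs))) {
    x <- segs[, k] - mean(segs[, k])
    for (mi in seq_along(lags)) {
      m_ <- lags[mi]
      for (ni in mi:length(lags)) {  # c3(m,n) = c3(n,m)
        n_ <- lags[ni]
        t0 <- max(1L, 1L - m_, 1L - n_)
        t1 <- min(wlen, wlen - m_, wlen - n_)
        v <- sum(x[t0:t1] * x[(t0 + m_):(t1 + m_)] * x[(t0 + n_):(t1 + n_)]) / wlen
        c3[mi, ni] <- c3[mi, ni] + v
        if (ni != mi) c3[ni, mi] <- c3[ni, mi] + v
      }
    }
  }
  c3 <- c3 / ncol(segs)
  w <- parzen_window(lags / L)
  taper <- outer(w, w) * parzen_window(outer(lags, lags, "-") / L)
  c3 <- c3 * taper
  # embed with wraparound for negative lags, then 2-D DFT
  A <- matrix(0, nfft, nfft)
  pos <- (lags %% nfft) + 1L
  A[pos, pos] <- c3
  Bfull <- stats::fft(A)
  m <- nfft %/% 2L + 1L
  new_bispectrum(Bfull[1:m, 1:m], bifrequency_grid(nfft, fs), "indirect",
                 ncol(segs))
}

parzen_window <- function(u) {
  au <- abs(u)
  ifelse(au <= 0.5, 1 - 6 * au^2 + 6 * au^3,
         ifelse(au <= 1, 2 * (1 - au)^3, 0))
}

new_bispectrum <- function(values, grid, method, n_segments) {
  structure(list(values = values, grid = grid, method = method,
                 n_segments = n_segments),
            class = "bispectrum")
}

#' @export
print.bispectrum <- function(x, ...) {
  pk <- pd_peak(x)
  cat(sprintf("<bispectrum> %s estimate, nfft=%d, %d segment(s)\n",
              x$method, x$grid$nfft, x$n_segments))
  cat(sprintf("  principal-domain |B| peak %.4g at (f1=%.2f, f2=%.2f) Hz\n",
              pk$value, pk$f1, pk$f2))
  invisible(x)
}

#' Bicoherence (normalized bispectrum) estimate
#'
#' Squared-coherence normalization: the squared magnitude of the averaged
#' triple product divided by `avg(|X(f1)X(f2)|^2) * avg(|X(f1+f2)|^2)`,
#' reported as its square root so every value lies in `[0, 1]` by the
#' Cauchy-Schwarz inequality. Cells whose denominator vanishes are defined as
#' 0 and flagged.
#'
#' @inheritParams bispectrum_direct
#' @return object of class `bicoherence`: real `values` in `[0,1]`, logical
#'   `flagged` matrix (zero-denominator cells), `grid`, `n_segments`.
#' @export
bicoherence <- function(windows, nfft = NULL, fs = NULL) {
  fs <- fs %||% infer_fs(windows)
  segs <- as_segment_matrix(windows)
  K <- ncol(segs)
  if (K < 8L) stop_hos("bicoherence needs at least 8 segments to average")
  nfft <- as.integer(nfft %||% nrow(segs))
  X <- segment_ffts(segs, nfft)
  m <- nfft %/% 2L + 1L
  idx <- sum_index(nfft)
  num <- matrix(0 + 0i, m, m)
  d12 <- matrix(0, m, m)
  d3 <- matrix(0, m, m)
  for (k in seq_len(K)) {
    Xh <- X[1:m, k]
    P12 <- outer(Xh, Xh)
    X3 <- matrix(X[idx, k], m, m)
    num <- num + P12 * Conj(X3)
    d12 <- d12 + Mod(P12)^2
    d3 <- d3 + Mod(X3)^2
  }
  num <- num / K; d12 <- d12 / K; d3 <- d3 / K
  den <- sqrt(d12 * d3)
  flagged <- den <= max(den) * 1e-12
  bic <- matrix(0, m, m)
  bic[!flagged] <- Mod(num[!flagged]) / den[!flagged]
  structure(list(values = bic, flagged = flagged,
                 grid = bifrequency_grid(nfft, fs), n_segments = K),
            class = "bicoherence")
}

#' @export
print.bicoherence <- function(x, ...) {
  pd <- principal_domain(x$grid)
  v <- x$values * pd$mask
  ij <- which(v == max(v), arr.ind = TRUE)[1L, ]
  cat(sprintf("<bicoherence> nfft=%d, %d segments\n", x$grid$nfft, x$n_segments))
  cat(sprintf("  principal-domain peak %.3f at (f1=%.2f, f2=%.2f) Hz\n",
              max(v), x$grid$freq_axis[ij[1L]], x$grid$freq_axis[ij[2L]]))
  invisible(x)
}

#' Principal domain of the discrete bispectrum
#'
#' The non-redundant inner triangle `{0 <= f2 <= f1, f1 + f2 <= fs/2}`. Its
#' images under the twelve bispectral symmetry transforms tile the band-limited
#' region of the bi-frequency plane (all three frequencies below Nyquist); see
#' [symmetry_coverage()].
#'
#' @param grid a [bifrequency_grid].
#' @return object of class `principal_domain` with a logical `mask` over the
#'   one-sided grid (rows `f1`, columns `f2`) and the `grid`.
#' @export
principal_domain <- function(grid) {
  stopifnot(inherits(grid, "bifrequency_grid"))
  m <- grid$nfft %/% 2L + 1L
  a <- 0:(m - 1L)
  mask <- outer(a, a, function(i, j) i >= j & (i + j) <= grid$nfft %/% 2L)
  structure(list(mask = mask, grid = grid), class = "principal_domain")
}

#' The twelve symmetry transforms of the bispectrum
#'
#' `B(f1, f2)` is invariant under the six permutations of the frequency triple
#' `(f1, f2, -f1-f2)` and conjugate-symmetric under negation, giving twelve
#' transforms of the bi-frequency plane.
#'
#' @return list of 12 functions; each maps integer frequency-index vectors
#'   `(a, b)` to a two-column matrix of transformed indices.
#' @export
bispectral_symmetries <- function() {
  perms <- list(
    function(a, b) cbind(a, b),
    function(a, b) cbind(b, a),
    function(a, b) cbind(a, -a - b),
    function(a, b) cbind(-a - b, a),
    function(a, b) cbind(b, -a - b),
    function(a, b) cbind(-a - b, b)
  )
  negs <- lapply(perms, function(f) function(a, b) -f(a, b))
  c(perms, negs)
}

#' Tiling check for the principal-domain symmetry expansion
#'
#' Applies the twelve symmetry transforms to every cell of the discrete
#' principal domain and checks that their images cover the band-limited
#' hexagon `{|f1|, |f2|, |f1+f2| <= fs/2}` of the bi-frequency plane, with
#' cells strictly inside the symmetry boundary lines covered exactly once.
#'
#' @param nfft grid transform length.
#' @return list with `n_transforms` (12), `covered` (TRUE if the hexagon is
#'   fully covered), `interior_once` (TRUE if interior multiplicity is 1) and
#'   the multiplicity `counts` matrix.
#' @export
symmetry_coverage <- function(nfft = 32L) {
  n2 <- as.integer(nfft) %/% 2L
  pd <- expand.grid(a = 0:n2, b = 0:n2)
  pd <- pd[pd$a >= pd$b & pd$a + pd$b <= n2, ]
  syms <- bispectral_symmetries()
  rng <- -n2:n2
  counts <- matrix(0L, length(rng), length(rng))
  for (f in syms) {
    im <- f(pd$a, pd$b)
    ii <- im[, 1L] + n2 + 1L
    jj <- im[, 2L] + n2 + 1L
    for (r in seq_along(ii)) counts[ii[r], jj[r]] <- counts[ii[r], jj[r]] + 1L
  }
  hex <- outer(rng, rng, function(a, b) abs(a + b) <= n2)
  boundary <- outer(rng, rng, function(a, b) {
    a == 0 | b == 0 | a == b | a == -b | a == -2 * b | b == -2 * a |
      abs(a) == n2 | abs(b) == n2 | abs(a + b) == n2
  })
  list(n_transforms = length(syms),
       covered = all(counts[hex] >= 1L),
       interior_once = all(counts[hex & !boundary] == 1L),
       counts = counts)
}

#' Principal-domain magnitude peak of a bispectrum
#'
#' @param bis a [bispectrum_direct()] / [bispectrum_indirect()] estimate.
#' @param exclude_dc drop the `f1 = 0` / `f2 = 0` lines (mean removal leaves
#'   them degenerate).
#' @return list with the peak `f1`, `f2` (Hz), grid indices `i`, `j` and
#'   magnitude `value`.
#' @export
pd_peak <- function(bis, exclude_dc = TRUE) {
  stopifnot(inherits(bis, "bispectrum") || inherits(bis, "bicoherence"))
  pd <- principal_domain(bis$grid)
  mag <- if (is.complex(bis$values)) Mod(bis$values) else bis$values
  mask <- pd$mask
  if (exclude_dc) mask[1L, ] <- mask[, 1L] <- FALSE
  mag[!mask] <- -Inf
  ij <- which(mag == max(mag), arr.ind = TRUE)[1L, , drop = TRUE]
  list(f1 = bis$grid$freq_axis[ij[1L]], f2 = bis$grid$freq_axis[ij[2L]],
       i = unname(ij[1L]), j = unname(ij[2L]), value = max(mag))
}

#' Hinich Gaussianity and linearity tests
#'
#' The Gaussianity statistic sums `2K * bicoherence^2` over the interior
#' principal-domain cells (K = number of averaged segments); under the
#' Gaussian null it is approximately central chi-squared with two degrees of
#' freedom per cell, and the probability of false alarm `pfa` is the upper
#' tail of that reference. The linearity check estimates the noncentrality
#' `lambda` from the mean of the same statistics and compares the sample
#' interquartile range against the spread implied by a constant-noncentrality
#' chi-squared model (a linear non-Gaussian process has constant
#' noncentrality across the plane).
#'
#' @inheritParams bicoherence
#' @return object of class `hinich_test` with fields `chi2_gauss`, `dof`,
#'   `pfa`, `lambda_lin`, `iqr_sample`, `iqr_theory`, `n_cells`, `n_segments`.
#' @export
hinich_test <- function(windows, nfft = NULL, fs = NULL) {
  fs <- fs %||% infer_fs(windows)
  segs <- as_segment_matrix(windows)
  if (all(apply(segs, 2L, stats::sd) == 0))
    stop_hos("degenerate (constant) input: Hinich statistics are undefined")
  bic <- bicoherence(segs, nfft = nfft, fs = fs)
  hinich_from_bicoherence(bic)
}

# Shared with the feature stage so the bicoherence estimate is reused.
hinich_from_bicoherence <- function(bic) {
  grid <- bic$grid
  n2 <- grid$nfft %/% 2L
  m <- n2 + 1L
  a <- 0:(m - 1L)
  interior <- outer(a, a, function(i, j) i >= j & j >= 1L & (i + j) < n2)
  use <- interior & !bic$flagged
  if (!any(use)) stop_hos("no usable principal-domain cells for the Hinich test")
  xstat <- 2 * bic$n_segments * bic$values[use]^2
  P <- sum(use)
  S <- sum(xstat)
  lambda <- max(mean(xstat) - 2, 0)
  q <- stats::quantile(xstat, c(0.25, 0.75), names = FALSE)
  qt <- stats::qchisq(c(0.25, 0.75), df = 2, ncp = lambda)
  structure(list(chi2_gauss = S, dof = 2L * P,
                 pfa = stats::pchisq(S, df = 2L * P, lower.tail = FALSE),
                 lambda_lin = lambda,
                 iqr_sample = q[2L] - q[1L], iqr_theory = qt[2L] - qt[1L],
                 n_cells = P, n_segments = bic$n_segments),
            class = "hinich_test")
}

#' @export
print.hinich_test <- function(x, ...) {
  cat("<hinich_test>\n")
  cat(sprintf("  Gaussianity: chi2 = %.2f on %d df, Pfa = %.3g\n",
              x$chi2_gauss, x$dof, x$pfa))
  cat(sprintf("  Linearity:   lambda = %.3f, IQR sample/theory = %.2f/%.2f\n",
              x$lambda_lin, x$iqr_sample, x$iqr_theory))
  invisible(x)
}

#' Contour plot of a bispectrum or bicoherence estimate
#'
#' @param x a `bispectrum` or `bicoherence` object.
#' @param main plot title.
#' @param ... passed to [graphics::filled.contour()].
#' @return invisibly, `x`.
#' @export
plot.bispectrum <- function(x, main = NULL, ...) {
  f <- x$grid$freq_axis
  graphics::filled.contour(
    f, f, Mod(x$values), xlab = "f1 (Hz)", ylab = "f2 (Hz)",
    main = main %||% sprintf("|B(f1,f2)| (%s estimate)", x$method), ...)
  invisible(x)
}

#' @rdname plot.bispectrum
#' @export
plot.bicoherence <- function(x, main = NULL, ...) {
  f <- x$grid$freq_axis
  graphics::filled.contour(
    f, f, x$values, xlab = "f1 (Hz)", ylab = "f2 (Hz)",
    main = main %||% "Bicoherence", zlim = c(0, 1), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_fs <- function(windows) {
  if (inherits(windows, "eeg_record")) return(windows$fs)
  if (is.list(windows) && length(windows) &&
      inherits(windows[[1L]], "eeg_window")) return(windows[[1L]]$fs)
  1
}
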