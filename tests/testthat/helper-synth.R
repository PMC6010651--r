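# Shared fixture builders; everything is generated in code at test time.

FS <- 173.61
DF64 <- FS / 64  # bi-frequency resolution of a 64-point segment grid

# 64-sample segments (columns) of a QPC record whose phase blocks align with
# the segmentation, at bin-aligned frequencies bin1*DF64 and bin2*DF64.
qpc_segments <- function(seed, coupled = TRUE, bin1 = 3, bin2 = 5,
                         noise_sd = 0.05, n_segments = 64, amplitudes = c(1, 1, 1)) {
  spec <- qpc_spec(bin1 * DF64, bin2 * DF64, amplitudes = amplitudes,
                   coupled = coupled, noise_sd = noise_sd, fs = FS,
                   n_samples = 64 * n_segments, seed = seed, block_len = 64L)
  matrix(gen_qpc_signal(spec)$samples, nrow = 64)
}

# Two-class feature data with exactly `inf` informative columns (class-mean
# shift `shift`), the rest pure noise.
planted_feature_data <- function(seed, n_per = 30, d = 47, inf = c(10, 33),
                                 shift = 1.5) {
  set.seed(seed)
  n <- 2 * n_per
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c(-1, 1), each = n_per)
  X[, inf] <- X[, inf] + shift * y
  list(X = X, y = y, inf = inf)
}

# Small synthetic Bonn-layout dataset shared across pipeline tests
# (built once per test run).
small_dataset_dir <- local({
  dir <- NULL
  function(records_per_class = 10L) {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "hoseeg-small-bonn")
      gen_bonn_like_dataset(
        default_bonn_recipes(records_per_class)[c("A", "D", "E")],
        dir, seed = 42L)
    }
    dir
  }
})

# Minimal classed estimate objects for feature-arithmetic tests.
fake_bispectrum <- function(values, grid) {
  hoseeg:::new_bispectrum(values, grid, "direct", 1L)
}
fake_bicoherence <- function(values, grid) {
  structure(list(values = values, flagged = values * 0 > 1, grid = grid,
                 n_segments = 8L),
            class = "bicoherence")
}
fake_hinich <- function(chi2 = 0, lambda = 0, pfa = 1) {
  structure(list(chi2_gauss = chi2, dof = 2L, pfa = pfa, lambda_lin = lambda,
                 iqr_sample = 0, iqr_theory = 0, n_cells = 1L, n_segments = 8L),
            class = "hinich_test")
}
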