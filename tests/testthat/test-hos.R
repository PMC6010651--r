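test_that("all-zero input gives an all-zero bispectrum by both methods", {
  z <- matrix(0, 64, 4)
  expect_true(all(Mod(bispectrum_direct(z)$values) == 0))
  expect_true(all(Mod(bispectrum_indirect(z, max_lag = 16)$values) == 0))
  expect_error(bispectrum_direct(list()), "empty")
})

test_that("bispectrum estimates are symmetric in (f1, f2)", {
  segs <- qpc_segments(2)
  for (b in list(bispectrum_direct(segs, fs = FS),
                 bispectrum_indirect(segs, max_lag = 31, fs = FS))) {
    expect_lt(max(Mod(b$values - t(b$values))), 1e-9 * max(Mod(b$values)))
  }
})

test_that("direct and indirect principal-domain peaks land on the coupled cell", {
  # spec frequencies 20 and 30 Hz; nearest 64-point grid cells are bins 7, 11
  spec <- qpc_spec(20, 30, coupled = TRUE, noise_sd = 0.05, fs = FS,
                   n_samples = 64 * 64, seed = 5, block_len = 64L)
  segs <- matrix(gen_qpc_signal(spec)$samples, 64)
  pd <- pd_peak(bispectrum_direct(segs, fs = FS))
  pi_ <- pd_peak(bispectrum_indirect(segs, max_lag = 31, nfft = 64, fs = FS))
  target <- sort(c(round(20 / DF64), round(30 / DF64)), decreasing = TRUE) + 1L
  expect_equal(c(pd$i, pd$j), target)
  expect_equal(c(pi_$i, pi_$j), target)
})

test_that("bispectrum magnitude scales cubically; bicoherence is scale-free", {
  segs <- qpc_segments(3, noise_sd = 0)
  b1 <- max(Mod(bispectrum_direct(segs, fs = FS)$values))
  b2 <- max(Mod(bispectrum_direct(2 * segs, fs = FS)$values))
  expect_lt(abs(b2 / b1 - 8), 0.01 * 8)
  c1 <- bicoherence(segs, fs = FS)$values
  c2 <- bicoherence(5 * segs, fs = FS)$values
  expect_lt(max(abs(c1 - c2)), 1e-9)
})

test_that("bicoherence stays within [0,1] and needs enough segments", {
  for (s in 1:5) {
    v <- bicoherence(qpc_segments(s, coupled = (s %% 2 == 0)), fs = FS)$values
    expect_true(all(v >= 0 & v <= 1 + 1e-9))
  }
  expect_error(bicoherence(matrix(rnorm(64 * 4), 64)), "8 segments")
})

test_that("zero-denominator bicoherence cells are flagged and reported as 0", {
  # band-limited input: a pure tone leaves most cells with ~zero denominator
  t <- (0:63) / FS
  segs <- vapply(1:8, function(k) cos(2 * pi * 5 * DF64 * t + k), numeric(64))
  b <- bicoherence(segs, fs = FS)
  expect_true(any(b$flagged))
  expect_true(all(b$values[b$flagged] == 0))
})

test_that("white-noise bicoherence background falls as segments are averaged", {
  bg <- sapply(c(8, 16, 64), function(K) {
    mean(sapply(1:8, function(s) {
      x <- matrix(gen_gaussian_record(64 * K, seed = 100 * K + s)$samples, 64)
      b <- bicoherence(x, fs = FS)
      pdm <- principal_domain(b$grid)$mask
      mean(b$values[pdm & !b$flagged])
    }))
  })
  expect_true(all(diff(bg) < 0))
})

test_that("principal domain is the inner triangle and 12 transforms tile the plane", {
  grid <- bifrequency_grid(8L, FS)
  pd <- principal_domain(grid)
  idx <- which(pd$mask, arr.ind = TRUE) - 1L  # to 0-based frequency indices
  expect_true(all(idx[, 1] >= idx[, 2]))
  expect_true(all(rowSums(idx) <= 4))
  expect_length(bispectral_symmetries(), 12L)

  cov <- symmetry_coverage(32L)
  expect_equal(cov$n_transforms, 12L)
  expect_true(cov$covered)
  expect_true(cov$interior_once)
})

test_that("Hinich test flags strong coupling and stays a probability", {
  h <- hinich_test(qpc_segments(4, TRUE, noise_sd = 0.05), fs = FS)
  expect_lt(h$pfa, 0.01)
  for (s in 1:5) {
    hg <- hinich_test(matrix(gen_gaussian_record(64 * 16, seed = s)$samples, 64))
    expect_gte(hg$pfa, 0)
    expect_lte(hg$pfa, 1)
    expect_gte(hg$lambda_lin, 0)
  }
  expect_error(hinich_test(matrix(1, 64, 16)), "degenerate")
})
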