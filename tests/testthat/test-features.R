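grid64 <- bifrequency_grid(64L, FS)
regions64 <- build_regions(band_scheme(), principal_domain(grid64))

test_that("four bands yield 10 disjoint pair regions plus the whole domain", {
  expect_length(regions64$regions, 11L)
  pairs <- regions64$regions[setdiff(names(regions64$regions), "whole")]
  expect_length(pairs, 10L)
  overlap <- Reduce(`+`, lapply(pairs, function(m) m * 1L))
  expect_true(all(overlap <= 1L))                      # mutually disjoint
  expect_true(all((overlap >= 1) <= regions64$regions$whole))  # union in whole
})

test_that("cells map to the unordered band pair of their centre frequencies", {
  grid <- bifrequency_grid(256L, FS)
  regs <- build_regions(band_scheme(), principal_domain(grid))
  f <- grid$freq_axis
  i <- which.min(abs(f - 2)); j <- i        # (2 Hz, 2 Hz) -> delta.delta
  expect_true(regs$regions$delta.delta[i, j])
  i <- which.min(abs(f - 10)); j <- which.min(abs(f - 2))
  expect_true(regs$regions$delta.alpha[i, j])
  expect_error(build_regions(band_scheme(c(0.5, 4, 8, 13, 100)),
                             principal_domain(grid)), "Nyquist")
})

test_that("the feature vocabulary is a fixed 47-name ordered set", {
  nm <- feature_names()
  expect_length(nm, 47L)
  expect_identical(nm[1:4], c("sumBis_delta.delta", "sumBis2_delta.delta",
                              "sumBic_delta.delta", "sumBic2_delta.delta"))
  expect_identical(tail(nm, 3), c("chi2", "lambda", "pfa"))
  expect_false(anyDuplicated(nm) > 0)
  # lossless serialization round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  v <- setNames(as.numeric(seq_along(nm)), nm)
  write.csv(t(v), f, row.names = FALSE)
  expect_identical(make.names(nm), colnames(read.csv(f, check.names = TRUE)))
})

test_that("zero estimates give zero sums but still 47 features", {
  m <- length(grid64$freq_axis)
  fv <- extract_features(fake_bispectrum(matrix(0 + 0i, m, m), grid64),
                         fake_bicoherence(matrix(0, m, m), grid64),
                         fake_hinich(), regions64)
  expect_length(fv, 47L)
  expect_true(all(fv[1:44] == 0))
})

test_that("single-cell bispectrum arithmetic sums into exactly one region", {
  m <- length(grid64$freq_axis)
  B <- matrix(0 + 0i, m, m)
  f <- grid64$freq_axis
  i <- which.min(abs(f - 2.7))              # a delta-band cell on the diagonal
  B[i, i] <- 2i                             # magnitude 2
  fv <- extract_features(fake_bispectrum(B, grid64),
                         fake_bicoherence(matrix(0, m, m), grid64),
                         fake_hinich(), regions64)
  expect_equal(unname(fv["sumBis_delta.delta"]), 2)
  expect_equal(unname(fv["sumBis2_delta.delta"]), 4)
  expect_equal(unname(fv["sumBis_whole"]), 2)
  other <- grep("^sumBis_", names(fv), value = TRUE)
  other <- setdiff(other, c("sumBis_delta.delta", "sumBis_whole"))
  expect_true(all(fv[other] == 0))
})

test_that("pair-region sums never exceed the whole-domain sum", {
  for (s in 1:3) {
    segs <- qpc_segments(s)
    fv <- window_features(as.vector(segs[, 1:4]), fs = FS)  # 256-sample window
    expect_length(fv, 47L)
    pair_sum <- sum(fv[grep("^sumBis_", names(fv))]) - fv["sumBis_whole"]
    expect_lte(pair_sum, fv[["sumBis_whole"]] + 1e-9)
  }
})

test_that("alpha-beta coupling raises the alpha-beta bicoherence feature", {
  wins <- function(seed, coupled) qpc_segments(seed, coupled, bin1 = 3, bin2 = 5)
  deltas <- sapply(1:8, function(s) {
    f <- function(cpl) {
      segs <- wins(s, cpl)
      bis <- bispectrum_direct(segs, fs = FS)
      bic <- bicoherence(segs, fs = FS)
      hin <- hinich_test(segs, fs = FS)
      extract_features(bis, bic, hin, regions64)[["sumBic2_alpha.beta"]]
    }
    f(TRUE) - f(FALSE)
  })
  expect_true(all(deltas > 0))
})

test_that("normalizer standardizes the training set and drops constants", {
  expect_equal(apply_normalizer(fit_normalizer(cbind(x = c(1, 2, 3))),
                                cbind(x = c(1, 2, 3)))[, 1],
               c(-1, 0, 1))
  set.seed(2)
  X <- cbind(a = rnorm(20, 5, 2), b = runif(20), const = rep(3, 20))
  expect_warning(norm <- fit_normalizer(X), "zero-variance")
  Z <- apply_normalizer(norm, X)
  expect_identical(colnames(Z), c("a", "b"))
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-9))
  expect_error(fit_normalizer(X[1, , drop = FALSE]), "two training")
})
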