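# Cheap deterministic fitness: rewards the two planted bits, penalizes size.
toy_fitness <- function(inf) {
  function(mask) 40 * mean(mask[inf]) + 20 * (1 - mean(mask))
}

test_that("an all-ones population returns all features after one generation", {
  cfg <- ga_config(population_size = 4L, generations = 1L, p_mutation = 0,
                   p_cross = 0, seed = 1L)
  init <- matrix(TRUE, 4L, 47L)
  res <- hoseeg:::ga_search(47L, function(m) 100 * mean(m), cfg, init = init)
  expect_true(all(res$mask))
  expect_equal(res$fitness, 100)
})

test_that("the GA is deterministic under a seed", {
  fit <- toy_fitness(c(3, 9))
  cfg <- ga_config(population_size = 10L, generations = 10L, seed = 42L)
  r1 <- hoseeg:::ga_search(20L, fit, cfg)
  r2 <- hoseeg:::ga_search(20L, fit, cfg)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$history, r2$history)
})

test_that("best-ever fitness is non-decreasing across generations (elitism)", {
  d <- planted_feature_data(7, n_per = 20)
  tr <- c(1:10, 21:30); va <- c(11:20, 31:40)
  fitfn <- make_lssvm_fitness(d$X[tr, ], d$y[tr], d$X[va, ], d$y[va],
                              kernel = kernel_spec("gaussian", sigma = sqrt(47)))
  res <- hoseeg:::ga_search(47L, fitfn,
                            ga_config(population_size = 12L, generations = 15L,
                                      seed = 3L))
  expect_true(all(diff(res$history$best) >= 0))
})

test_that("without crossover, mutation or elitism the population is static", {
  cfg <- ga_config(population_size = 6L, generations = 5L, p_cross = 0,
                   p_mutation = 0, elitism = 0L, seed = 9L)
  res <- hoseeg:::ga_search(15L, function(m) sum(m), cfg)
  # tournament replacement can only reshuffle existing chromosomes, so the
  # mean fitness can drift, but no new genetic material can appear:
  # the best-ever individual must already exist at initialization
  expect_equal(res$history$best[1], res$fitness)
})

test_that("all-zero chromosomes score fitness 0 and are never the winner", {
  res <- hoseeg:::ga_search(5L, function(m) 50,
                            ga_config(population_size = 4L, generations = 2L,
                                      seed = 2L))
  expect_true(any(res$mask))
})

test_that("the GA recovers two planted informative features", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(500 + s)
    d <- 47; inf <- c(10, 33)
    Xtr <- matrix(rnorm(60 * d), 60, d); ytr <- rep(c(-1, 1), each = 30)
    Xva <- matrix(rnorm(40 * d), 40, d); yva <- rep(c(-1, 1), each = 20)
    Xtr[, inf] <- Xtr[, inf] + 1.5 * ytr
    Xva[, inf] <- Xva[, inf] + 1.5 * yva
    fitfn <- make_lssvm_fitness(Xtr, ytr, Xva, yva,
                                kernel = kernel_spec("gaussian", sigma = sqrt(d)))
    res <- ga_select(Xtr, ytr,
                     ga_config(population_size = 30L, generations = 40L,
                               seed = s),
                     fitness_fn = fitfn)
    hits <- hits + all(res$mask[inf])
  }
  expect_gte(hits, 4L)
})

test_that("t ranking matches the closed-form statistic and orders by p", {
  set.seed(1)
  X <- cbind(strong = rnorm(200), noise = rnorm(200))
  y <- rep(c(0, 1), each = 100)
  X[, "strong"] <- X[, "strong"] + 5 * y
  r <- ttest_rank(X, y)
  expect_identical(r$feature[1], "strong")
  expect_lt(r$p[1], 1e-10)
  expect_true(r$pass[1])
  # closed-form oracle via stats::t.test on the same column
  tt <- t.test(X[y == 0, "strong"], X[y == 1, "strong"], var.equal = TRUE)
  expect_equal(r$t[r$feature == "strong"], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p[r$feature == "strong"], tt$p.value, tolerance = 1e-12)
})

test_that("ranking is invariant under affine rescaling of a feature", {
  set.seed(4)
  X <- matrix(rnorm(120), 60, 2)
  y <- rep(c(0, 1), 30)
  r1 <- ttest_rank(X, y)
  X2 <- X; X2[, 1] <- 1000 * X2[, 1] - 7
  r2 <- ttest_rank(X2, y)
  expect_equal(abs(r1$t), abs(r2$t), tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("pure-noise features pass the 0.001 screen at about the nominal rate", {
  set.seed(12)
  X <- matrix(rnorm(200 * 1000), 200, 1000)
  y <- rep(c(0, 1), each = 100)
  frac <- mean(ttest_rank(X, y)$pass)
  expect_gte(frac, 0)
  expect_lte(frac, 0.005)
})

test_that("the published 12 p-values keep 10 features at the 0.001 rule", {
  p <- c(8.64e-10, 6.15e-05, 1.38e-06, 1.12e-02, 1.78e-04, 4.22e-07,
         0, 0, 2.61e-09, 7.21e-03, 8.11e-06, 0)
  expect_equal(sum(p < 0.001), 10L)
})

test_that("single-class input is rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(ttest_rank(X, rep(1, 10)), "two classes")
})
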