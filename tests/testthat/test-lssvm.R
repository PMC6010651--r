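test_that("kernels satisfy their defining identities", {
  g <- kernel_spec("gaussian", sigma = 2)
  x <- c(1, 2, 3)
  expect_equal(kernel_eval(g, x, x), 1)
  expect_equal(kernel_eval(g, x, c(0, 0, 0)), exp(-sum(x^2) / 4))
  p1 <- kernel_spec("polynomial", degree = 1L, offset = 0)
  expect_equal(kernel_eval(p1, x, c(4, 5, 6)), sum(x * c(4, 5, 6)))
  expect_error(kernel_eval(g, x, c(1, 2)), "dimension")
  expect_error(kernel_spec("gaussian", sigma = 0), "sigma")
})

test_that("gaussian Gram matrices are symmetric positive semidefinite", {
  set.seed(6)
  X <- matrix(rnorm(10 * 3), 10, 3)
  K <- kernel_matrix(kernel_spec("gaussian", sigma = 1.5), X)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("a separable two-point problem is fit exactly", {
  fit <- lssvm(matrix(c(-1, 1), 2, 1), c(-1, 1), gamma = 10)
  expect_equal(predict(fit), c(-1, 1))
})

test_that("XOR is solved and the dual matches an independent block solve", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(-1, 1, 1, -1)
  kern <- kernel_spec("gaussian", sigma = 0.5)
  fit <- lssvm(X, y, gamma = 100, kernel = kern)
  expect_equal(predict(fit, X), y)

  # independent oracle: block elimination of the KKT system
  # H = y y' * K + I/gamma;  b = (y' H^-1 1)/(y' H^-1 y);  a = H^-1 (1 - b y)
  K <- outer(seq_len(4), seq_len(4),
             Vectorize(function(i, j) kernel_eval(kern, X[i, ], X[j, ])))
  H <- K * tcrossprod(y) + diag(4) / 100
  Hi1 <- solve(H, rep(1, 4)); Hiy <- solve(H, y)
  b <- sum(y * Hi1) / sum(y * Hiy)
  a <- solve(H, 1 - b * y)
  expect_lt(sqrt(sum((fit$alpha - a)^2)) / sqrt(sum(a^2)), 1e-8)
  expect_lt(abs(fit$b - b), 1e-8)
  # residual of the dual system itself
  res <- H %*% fit$alpha + fit$b * y - 1
  expect_lt(sqrt(sum(res^2)), 1e-8)
  expect_equal(sum(fit$alpha * y), 0, tolerance = 1e-10)
})

test_that("conflicting duplicate points give a near-zero decision value", {
  X <- rbind(c(0, 0), c(0, 0))
  fit <- lssvm(X, c(-1, 1), gamma = 0.01)
  expect_lt(abs(predict(fit, rbind(c(0, 0)), type = "decision")), 1e-6)
})

test_that("training accuracy reaches 100% on separable data as gamma grows", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, -2, 0.5), 20), matrix(rnorm(40, 2, 0.5), 20))
  y <- rep(c(-1, 1), each = 20)
  fit <- lssvm(X, y, gamma = 1e4, kernel = kernel_spec("gaussian", sigma = 2))
  expect_equal(mean(predict(fit) == y), 1)
})

test_that("OVO and ECOC reduce exactly to the binary machine when k = 2", {
  set.seed(9)
  X <- rbind(matrix(rnorm(30, -1), 15), matrix(rnorm(30, 1), 15))
  y <- factor(rep(c("a", "b"), each = 15))
  Xt <- matrix(rnorm(40), 20)
  bin <- lssvm(X, y, gamma = 10, kernel = kernel_spec("gaussian", sigma = 2))
  for (coding in c("ovo", "ecoc")) {
    mc <- lssvm_multiclass(X, y, coding, gamma = 10,
                           kernel = kernel_spec("gaussian", sigma = 2))
    expect_length(mc$machines, 1L)
    expect_identical(predict(mc, Xt), predict(bin, Xt))
  }
})

test_that("three separable blobs are classified perfectly by both codings", {
  set.seed(5)
  blob <- function(cx, cy, n = 25) cbind(rnorm(n, cx, 0.25), rnorm(n, cy, 0.25))
  X <- rbind(blob(0, 0), blob(3, 0), blob(0, 3))
  y <- factor(rep(c("h", "i", "s"), each = 25))
  test_idx <- c(1:8, 26:33, 51:58)
  for (coding in c("ovo", "ecoc")) {
    fit <- lssvm_multiclass(X[-test_idx, ], y[-test_idx], coding, gamma = 100,
                            kernel = kernel_spec("gaussian", sigma = 1))
    expect_equal(mean(predict(fit, X[test_idx, ]) == y[test_idx]), 1)
  }
})

test_that("the exhaustive three-class ECOC code has three distinct columns", {
  sch <- coding_scheme("ecoc", 3L)
  M <- sch$code_matrix
  expect_equal(dim(M), c(3L, 3L))
  expect_equal(nrow(unique(M)), 3L)
  ham <- as.matrix(dist(M, method = "manhattan")) / 2
  expect_true(all(ham[upper.tri(ham)] >= 1))
  expect_length(coding_scheme("ovo", 4L)$pairs[1, ], 6L)  # C(4,2) machines
})

test_that("metrics follow the sensitivity/specificity/accuracy formulas", {
  m <- compute_metrics(c(TP = 50, TN = 45, FP = 5, FN = 0))
  expect_equal(m$per_class$sensitivity, 100)
  expect_equal(m$per_class$specificity, 90)
  expect_equal(m$total_accuracy, 95)

  perfect <- compute_metrics(confusion_counts(rep(c("x", "y"), 10),
                                              rep(c("x", "y"), 10)))
  expect_true(all(perfect$per_class$sensitivity == 100))
  expect_equal(perfect$total_accuracy, 100)

  wrong <- compute_metrics(confusion_counts(rep(c("x", "y"), 10),
                                            rep(c("y", "x"), 10)))
  expect_equal(wrong$total_accuracy, 0)

  undef <- compute_metrics(c(TP = 0, TN = 9, FP = 1, FN = 0))
  expect_true(is.na(undef$per_class$sensitivity))
})

test_that("metrics are invariant to sample order", {
  set.seed(8)
  truth <- sample(c("p", "q", "r"), 60, replace = TRUE)
  pred <- sample(c("p", "q", "r"), 60, replace = TRUE)
  perm <- sample(60)
  m1 <- compute_metrics(confusion_counts(truth, pred))
  m2 <- compute_metrics(confusion_counts(truth[perm], pred[perm]))
  expect_equal(m1$per_class, m2$per_class)
  expect_equal(m1$total_accuracy, m2$total_accuracy)
})
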