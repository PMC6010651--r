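#' Kernel specification
#'
#' Gaussian RBF `exp(-||x-z||^2 / sigma^2)` or polynomial
#' `(x.z + offset)^degree`.
#'
#' @param kind `"gaussian"` or `"polynomial"`.
#' @param sigma Gaussian bandwidth (> 0).
#' @param degree polynomial degree (>= 1).
#' @param offset polynomial offset.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("gaussian", "polynomial"), sigma = 1,
                        degree = 2L, offset = 1) {
  kind <- match.arg(kind)
  if (kind == "gaussian" && sigma <= 0) stop_hos("sigma must be > 0")
  if (kind == "polynomial" && degree < 1) stop_hos("degree must be >= 1")
  structure(list(kind = kind, sigma = sigma, degree = as.integer(degree),
                 offset = offset),
            class = "kernel_spec")
}

#' Evaluate a kernel between two points
#'
#' @param spec a [kernel_spec].
#' @param x,z numeric vectors of equal length.
#' @return scalar kernel value.
#' @export
kernel_eval <- function(spec, x, z) {
  if (length(x) != length(z)) stop_hos("kernel arguments differ in dimension")
  kernel_matrix(spec, matrix(x, 1L), matrix(z, 1L))[1L, 1L]
}

#' Kernel Gram matrix
#'
#' @param spec a [kernel_spec].
#' @param X,Z numeric matrices with points in rows (`Z` defaults to `X`).
#' @return `nrow(X)` x `nrow(Z)` kernel matrix.
#' @export
kernel_matrix <- function(spec, X, Z = X) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) stop_hos("kernel arguments differ in dimension")
  if (spec$kind == "gaussian") {
    d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
    d2[d2 < 0] <- 0
    exp(-d2 / spec$sigma^2)
  } else {
    (tcrossprod(X, Z) + spec$offset)^spec$degree
  }
}

#' Least-squares support vector machine (binary)
#'
#' Solves the LS-SVM dual system
#' \deqn{\left[\begin{array}{cc} 0 & y^T \\ y & \Omega + I/\gamma \end{array}\right]
#'       \left[\begin{array}{c} b \\ \alpha \end{array}\right] =
#'       \left[\begin{array}{c} 0 \\ 1 \end{array}\right]}
#' with \eqn{\Omega_{ij} = y_i y_j K(x_i, x_j)}. The decision value is
#' \eqn{d(x) = \sum_i \alpha_i y_i K(x, x_i) + b} and the predicted label is
#' its sign.
#'
#' @param x numeric training matrix (points in rows).
#' @param y labels: +1/-1 numeric, logical, or a two-level factor (first
#'   level maps to -1).
#' @param gamma regularization (> 0); larger fits the training data harder.
#' @param kernel a [kernel_spec].
#' @return object of class `lssvm` with `alpha`, `b`, the stored training
#'   inputs and label coding.
#' @export
lssvm <- function(x, y, gamma = 10, kernel = kernel_spec("gaussian", sigma = 1)) {
  x <- as.matrix(x)
  cod <- code_binary(y)
  yv <- cod$y
  if (gamma <= 0) stop_hos("gamma must be > 0")
  if (length(unique(yv)) < 2L) stop_hos("need samples from both classes")
  n <- nrow(x)
  K <- kernel_matrix(kernel, x)
  Omega <- K * tcrossprod(yv) + diag(n) / gamma
  A <- rbind(c(0, yv), cbind(yv, Omega))
  sol <- tryCatch(solve(A, c(0, rep(1, n))), error = function(e)
    stop_hos("LS-SVM system is numerically singular (condition estimate ",
             format(kappa(A)), "): ", conditionMessage(e)))
  structure(list(alpha = sol[-1L], b = sol[1L], gamma = gamma,
                 kernel = kernel, x = x, y = yv, levels = cod$levels),
            class = "lssvm")
}

# Map labels to {-1, +1}; remember factor levels for decoding.
code_binary <- function(y) {
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    if (nlevels(f) != 2L) stop_hos("binary LS-SVM needs exactly two classes")
    list(y = ifelse(as.integer(f) == 2L, 1, -1), levels = levels(f))
  } else {
    yv <- as.numeric(y)
    if (!all(yv %in% c(-1, 1))) stop_hos("numeric labels must be -1/+1")
    list(y = yv, levels = NULL)
  }
}

#' Decision values and class predictions from an LS-SVM
#'
#' @param object a fitted [lssvm()].
#' @param newdata matrix of points in rows (training inputs by default).
#' @param type `"class"` for labels, `"decision"` for raw decision values.
#' @param ... unused.
#' @return numeric labels (or original factor levels), or decision values.
#' @export
predict.lssvm <- function(object, newdata = object$x,
                          type = c("class", "decision"), ...) {
  type <- match.arg(type)
  K <- kernel_matrix(object$kernel, as.matrix(newdata), object$x)
  d <- drop(K %*% (object$alpha * object$y)) + object$b
  if (type == "decision") return(d)
  cls <- ifelse(d >= 0, 1, -1)
  if (!is.null(object$levels))
    factor(object$levels[(cls + 3) / 2], levels = object$levels)
  else cls
}

#' @export
coef.lssvm <- function(object, ...) c(b = object$b, alpha = object$alpha)

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf("<lssvm> %d support values, gamma=%g, %s kernel\n",
              length(x$alpha), x$gamma, x$kernel$kind))
  invisible(x)
}

#' @export
summary.lssvm <- function(object, ...) {
  pred <- predict(object)
  truth <- if (!is.null(object$levels))
    factor(object$levels[(object$y + 3) / 2], levels = object$levels)
  else object$y
  acc <- 100 * mean(pred == truth)
  cat(sprintf("LS-SVM: n=%d, gamma=%g, %s kernel; training accuracy %.1f%%\n",
              length(object$alpha), object$gamma, object$kernel$kind, acc))
  invisible(list(training_accuracy = acc))
}

#' Multiclass coding scheme
#'
#' One-versus-one (`"ovo"`): one machine per class pair, majority vote.
#' Error-correcting output codes (`"ecoc"`): one machine per column of a
#' +/-1 code matrix, decoding by minimum Hamming distance. For three classes
#' the exhaustive three-column code is used; for two classes both schemes
#' reduce exactly to the single binary machine; for k > 3 a seeded random
#' dense code with `2k` columns is drawn (distinct rows, no constant column).
#'
#' @param kind `"ovo"` or `"ecoc"`.
#' @param k number of classes.
#' @param seed seed for random dense codes (k > 3 ECOC only).
#' @return object of class `coding_scheme` (with `pairs` for OVO or
#'   `code_matrix` for ECOC).
#' @export
coding_scheme <- function(kind = c("ovo", "ecoc"), k, seed = NULL) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (k < 2L) stop_hos("need k >= 2 classes")
  if (kind == "ovo") {
    pairs <- utils::combn(k, 2L)
    structure(list(kind = "ovo", k = k, pairs = pairs), class = "coding_scheme")
  } else {
    M <- ecoc_code(k, seed)
    structure(list(kind = "ecoc", k = k, code_matrix = M), class = "coding_scheme")
  }
}

ecoc_code <- function(k, seed = NULL) {
  if (k == 2L) return(matrix(c(-1, 1), 2L, 1L))
  if (k == 3L) {
    # exhaustive code: 2^(k-1) - 1 = 3 columns
    return(matrix(c(1, 1, 1,
                    -1, -1, 1,
                    -1, 1, -1), 3L, 3L, byrow = TRUE))
  }
  with_seed(seed %||% 1L, {
    repeat {
      M <- matrix(sample(c(-1, 1), k * 2L * k, replace = TRUE), k, 2L * k)
      rows_ok <- nrow(unique(M)) == k && nrow(unique(-M)) == k &&
        !any(duplicated(rbind(M, -M)))
      cols_ok <- all(abs(colSums(M)) < k)
      if (rows_ok && cols_ok) return(M)
    }
  })
}

#' Multiclass LS-SVM
#'
#' Trains the binary machines a [coding_scheme] prescribes and wires their
#' decisions into a k-class predictor. OVO predicts by majority vote; ECOC by
#' minimum Hamming distance between the sign vector of the machines and the
#' class codewords. Ties are broken by the largest summed decision margin.
#'
#' @param x numeric training matrix.
#' @param y class labels (factor or coercible).
#' @param coding `"ovo"`, `"ecoc"`, or a [coding_scheme].
#' @param gamma regularization.
#' @param kernel a [kernel_spec].
#' @param seed seed for random ECOC codes (k > 3).
#' @return object of class `lssvm_mc`.
#' @export
lssvm_multiclass <- function(x, y, coding = c("ovo", "ecoc"), gamma = 10,
                             kernel = kernel_spec("gaussian", sigma = 1),
                             seed = NULL) {
  x <- as.matrix(x)
  f <- factor(y)
  k <- nlevels(f)
  if (k < 2L) stop_hos("need at least two classes")
  scheme <- if (inherits(coding, "coding_scheme")) coding
  else coding_scheme(match.arg(coding), k, seed = seed)
  machines <- list()
  if (scheme$kind == "ovo") {
    for (c in seq_len(ncol(scheme$pairs))) {
      i <- scheme$pairs[1L, c]; j <- scheme$pairs[2L, c]
      sel <- as.integer(f) %in% c(i, j)
      yy <- ifelse(as.integer(f)[sel] == j, 1, -1)
      machines[[c]] <- lssvm(x[sel, , drop = FALSE], yy, gamma, kernel)
    }
  } else {
    M <- scheme$code_matrix
    for (c in seq_len(ncol(M))) {
      yy <- M[as.integer(f), c]
      machines[[c]] <- lssvm(x, yy, gamma, kernel)
    }
  }
  structure(list(machines = machines, scheme = scheme, levels = levels(f),
                 gamma = gamma, kernel = kernel),
            class = "lssvm_mc")
}

#' @export
predict.lssvm_mc <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  k <- length(object$levels)
  D <- vapply(object$machines, function(m)
    predict(m, newdata, type = "decision"), numeric(n))
  D <- matrix(D, nrow = n)
  scheme <- object$scheme
  if (scheme$kind == "ovo") {
    votes <- matrix(0L, n, k)
    margin <- matrix(0, n, k)
    for (c in seq_len(ncol(scheme$pairs))) {
      i <- scheme$pairs[1L, c]; j <- scheme$pairs[2L, c]
      win <- ifelse(D[, c] >= 0, j, i)
      for (r in seq_len(n)) votes[r, win[r]] <- votes[r, win[r]] + 1L
      margin[, i] <- margin[, i] - D[, c]
      margin[, j] <- margin[, j] + D[, c]
    }
    pick <- vapply(seq_len(n), function(r) {
      top <- which(votes[r, ] == max(votes[r, ]))
      if (length(top) > 1L) top <- top[which.max(margin[r, top])]
      top[1L]
    }, 1L)
  } else {
    M <- scheme$code_matrix
    S <- sign(D); S[S == 0] <- 1
    pick <- vapply(seq_len(n), function(r) {
      ham <- colSums(t(M) != S[r, ])      # Hamming distance to each codeword
      top <- which(ham == min(ham))
      if (length(top) > 1L) {
        sc <- drop(M[top, , drop = FALSE] %*% D[r, ])  # summed margin
        top <- top[which.max(sc)]
      }
      top[1L]
    }, 1L)
  }
  factor(object$levels[pick], levels = object$levels)
}

#' @export
print.lssvm_mc <- function(x, ...) {
  cat(sprintf("<lssvm_mc> %d classes, %s coding, %d machine(s), %s kernel\n",
              length(x$levels), x$scheme$kind, length(x$machines),
              x$kernel$kind))
  invisible(x)
}

#' LS-SVM wrapper fitness for feature selection
#'
#' Builds the callback [ga_select()] expects: given a feature mask, train an
#' LS-SVM (binary or multiclass as the labels require) on the masked training
#' features and return the validation accuracy in percent.
#'
#' @param X_train,y_train training partition.
#' @param X_val,y_val validation partition used for scoring.
#' @param gamma,kernel classifier hyperparameters.
#' @param coding multiclass coding when more than two classes.
#' @return function(mask) -> accuracy in `[0, 100]`.
#' @export
make_lssvm_fitness <- function(X_train, y_train, X_val, y_val, gamma = 10,
                               kernel = kernel_spec("gaussian", sigma = 1),
                               coding = "ovo") {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  f_train <- factor(y_train)
  f_val <- factor(y_val, levels = levels(f_train))
  k <- nlevels(f_train)
  function(mask) {
    mask <- as.logical(mask)
    if (!any(mask)) return(0)
    fit <- if (k == 2L)
      lssvm(X_train[, mask, drop = FALSE], f_train, gamma, kernel)
    else
      lssvm_multiclass(X_train[, mask, drop = FALSE], f_train, coding,
                       gamma, kernel)
    pred <- predict(fit, X_val[, mask, drop = FALSE])
    100 * mean(pred == f_val)
  }
}
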