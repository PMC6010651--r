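#' Genetic-algorithm configuration
#'
#' Defaults follow the published recipe: crossover probability 0.4, per-bit
#' mutation probability 0.05, 100 generations. Population size, tournament
#' selection and single-elite replacement are conventional choices exposed
#' here.
#'
#' @param population_size number of chromosomes.
#' @param p_cross single-point crossover probability.
#' @param p_mutation per-bit flip probability.
#' @param generations number of generations.
#' @param elitism how many best chromosomes are carried over unchanged.
#' @param seed integer seed; the whole run is reproducible under it.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, p_cross = 0.4, p_mutation = 0.05,
                      generations = 100L, elitism = 1L, seed = NULL) {
  if (p_cross < 0 || p_cross > 1 || p_mutation < 0 || p_mutation > 1)
    stop_hos("probabilities must lie in [0, 1]")
  if (generations < 1L) stop_hos("generations must be >= 1")
  structure(list(population_size = as.integer(population_size),
                 p_cross = p_cross, p_mutation = p_mutation,
                 generations = as.integer(generations),
                 elitism = as.integer(elitism), seed = seed),
            class = "ga_config")
}

#' Genetic-algorithm wrapper feature selection
#'
#' Searches binary feature masks with a generational GA: random initial
#' population, fitness = classification accuracy returned by `fitness_fn` on
#' the masked features, tournament parent selection (size 2), single-point
#' crossover at rate `p_cross`, independent per-bit mutation at rate
#' `p_mutation`, generational replacement with elitism, stop after a fixed
#' number of generations. All-zero chromosomes get fitness 0 and are never
#' selected. Fitness values are cached per mask, so repeated masks cost
#' nothing to re-evaluate.
#'
#' @param X numeric feature matrix (rows = instances); columns are the
#'   candidate features the chromosome bits switch on and off.
#' @param y class labels (>= 2 classes), one per row of `X`.
#' @param cfg a [ga_config].
#' @param fitness_fn function taking a logical mask over the columns of `X`
#'   and returning a classification accuracy in `[0, 100]` (conventionally
#'   the validation-set accuracy of the wrapped classifier). When `NULL`, a
#'   default LS-SVM wrapper fitness is built with
#'   [make_lssvm_fitness()] on an internal stratified 70/30 train/validation
#'   split of `X`.
#' @param init optional logical matrix (`population_size` x `ncol(X)`) of
#'   starting chromosomes; random by default.
#' @return object of class `ga_selection`: best-ever `mask` (logical),
#'   `fitness`, per-generation `history` (best/mean fitness) and `n_evals`.
#' @export
ga_select <- function(X, y, cfg = ga_config(), fitness_fn = NULL, init = NULL) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop_hos("need at least two classes")
  if (is.null(fitness_fn)) {
    idx <- with_seed(derive_seed(cfg$seed %||% 0L, "ga-fitness-split"), {
      unlist(lapply(split(seq_along(y), y), function(ix)
        sample(ix, max(1L, round(0.3 * length(ix))))))
    })
    fitness_fn <- make_lssvm_fitness(X[-idx, , drop = FALSE], y[-idx],
                                     X[idx, , drop = FALSE], y[idx])
  }
  ga_search(ncol(X), fitness_fn, cfg, init)
}

# Core mask search; `fitness_fn(mask)` must return accuracy in [0, 100].
ga_search <- function(n_features, fitness_fn, cfg = ga_config(), init = NULL) {
  stopifnot(is.function(fitness_fn), inherits(cfg, "ga_config"))
  n <- as.integer(n_features)
  if (n < 1L) stop_hos("n_features must be >= 1")
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  n_evals <- 0L
  evaluate <- function(mask) {
    if (!any(mask)) return(0)
    key <- paste(as.integer(mask), collapse = "")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    val <- fitness_fn(mask)
    if (!is.finite(val)) val <- 0
    n_evals <<- n_evals + 1L
    assign(key, val, envir = cache)
    val
  }
  with_seed(cfg$seed, {
    P <- cfg$population_size
    pop <- init %||% matrix(stats::runif(P * n) < 0.5, P, n)
    fit <- apply(pop, 1L, evaluate)
    best_mask <- pop[which.max(fit), ]
    best_fit <- max(fit)
    history <- matrix(NA_real_, cfg$generations, 2L,
                      dimnames = list(NULL, c("best", "mean")))
    for (g in seq_len(cfg$generations)) {
      newpop <- matrix(FALSE, P, n)
      n_elite <- min(cfg$elitism, P)
      if (n_elite > 0L)
        newpop[seq_len(n_elite), ] <- pop[order(-fit)[seq_len(n_elite)], ]
      i <- n_elite
      while (i < P) {
        pa <- tournament(fit)
        pb <- tournament(fit)
        c1 <- pop[pa, ]; c2 <- pop[pb, ]
        if (stats::runif(1) < cfg$p_cross && n > 1L) {
          cut <- sample.int(n - 1L, 1L)
          tmp <- c1
          c1 <- c(c1[1:cut], c2[(cut + 1L):n])
          c2 <- c(c2[1:cut], tmp[(cut + 1L):n])
        }
        c1 <- xor(c1, stats::runif(n) < cfg$p_mutation)
        c2 <- xor(c2, stats::runif(n) < cfg$p_mutation)
        i <- i + 1L; newpop[i, ] <- c1
        if (i < P) { i <- i + 1L; newpop[i, ] <- c2 }
      }
      pop <- newpop
      fit <- apply(pop, 1L, evaluate)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_mask <- pop[which.max(fit), ]
      }
      history[g, ] <- c(best_fit, mean(fit))
    }
    structure(list(mask = as.logical(best_mask), fitness = best_fit,
                   history = as.data.frame(history), n_evals = n_evals,
                   config = cfg),
              class = "ga_selection")
  })
}

tournament <- function(fit, size = 2L) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  cand[which.max(fit[cand])]
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("<ga_selection> %d/%d features, fitness %.2f%%, %d evaluations\n",
              sum(x$mask), length(x$mask), x$fitness, x$n_evals))
  invisible(x)
}

#' Student-t feature ranking
#'
#' Two-sample t statistic and two-sided p-value per feature column, features
#' sorted by ascending p. Features with `p < alpha` (default 0.001) carry the
#' pass flag.
#'
#' @param X numeric feature matrix (rows = instances).
#' @param y binary labels (two distinct values; each with >= 2 samples).
#' @param alpha pass threshold on the p-value.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return object of classes `rank_result`/`data.frame` with columns
#'   `feature`, `t`, `p`, `pass`, sorted by ascending p.
#' @export
ttest_rank <- function(X, y, alpha = 0.001, var_equal = TRUE) {
  X <- as.matrix(X)
  cls <- unique(y)
  if (length(cls) != 2L)
    stop_hos("ttest_rank needs exactly two classes; got ", length(cls))
  a <- X[y == cls[1L], , drop = FALSE]
  b <- X[y == cls[2L], , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) stop_hos("each class needs >= 2 samples")
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2L, stats::var); v2 <- apply(b, 2L, stats::var)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, ncol(X))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  nm <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  out <- data.frame(feature = nm, t = t, p = p, pass = p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  attr(out, "alpha") <- alpha
  class(out) <- c("rank_result", "data.frame")
  out
}
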