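#' Experiment specification
#'
#' The five canonical set-to-class designs on the A-E corpus layout:
#' \describe{
#'   \item{1}{A,B = healthy; C,D = interictal; E = ictal (3 classes)}
#'   \item{2}{A = healthy; D = interictal; E = ictal (3 classes)}
#'   \item{3}{A = healthy; E = ictal (binary)}
#'   \item{4}{A,B,C,D = non-seizure; E = seizure (binary)}
#'   \item{5}{D = interictal; E = ictal (binary)}
#' }
#' Feature vectors are split 60% training / 5% validation / 35% testing,
#' stratified per class.
#'
#' @param id experiment number 1-5, or `NULL` when `set_class` is given.
#' @param set_class named character vector mapping set ids to class labels
#'   (overrides the preset).
#' @param fractions named split fractions (must sum to 1).
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(id = 1L, set_class = NULL,
                            fractions = c(train = 0.60, validation = 0.05,
                                          test = 0.35),
                            seed = 1L) {
  presets <- list(
    `1` = c(A = "healthy", B = "healthy", C = "interictal", D = "interictal",
            E = "ictal"),
    `2` = c(A = "healthy", D = "interictal", E = "ictal"),
    `3` = c(A = "healthy", E = "ictal"),
    `4` = c(A = "non-seizure", B = "non-seizure", C = "non-seizure",
            D = "non-seizure", E = "seizure"),
    `5` = c(D = "interictal", E = "ictal")
  )
  if (is.null(set_class)) {
    id <- as.integer(id)
    if (!id %in% 1:5) stop_hos("experiment id must be 1..5")
    set_class <- presets[[as.character(id)]]
  }
  if (is.null(names(set_class)) || anyDuplicated(names(set_class)))
    stop_hos("set_class must map each set id to exactly one class")
  if (abs(sum(fractions) - 1) > 1e-9) stop_hos("split fractions must sum to 1")
  structure(list(id = id, set_class = set_class, fractions = fractions,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Stratified train/validation/test split
#'
#' Random per-class assignment at the spec's fractions, with exact per-class
#' counts resolved by the largest-remainder rule (so a 1600-vector class at
#' 60/5/35 gives exactly 960/80/560).
#'
#' @param n_per_class named integer vector of class sizes.
#' @param spec an [experiment_spec] (supplies fractions and seed).
#' @return object of class `split_assignment`: list per class of partition
#'   tags (`"train"`, `"validation"`, `"test"`), plus a `counts` matrix.
#' @export
make_split <- function(n_per_class, spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (any(n_per_class <= 0)) stop_hos("class sizes must be positive")
  fr <- spec$fractions
  tags <- names(fr)
  assign_one <- function(n) {
    base <- floor(n * fr)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(n * fr - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    sample(rep(tags, times = base))
  }
  out <- with_seed(derive_seed(spec$seed, "split"),
                   lapply(n_per_class, assign_one))
  counts <- t(vapply(out, function(a) table(factor(a, levels = tags)),
                     stats::setNames(numeric(length(tags)), tags)))
  structure(list(assignment = out, counts = counts, fractions = fr),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>\n")
  print(x$counts)
  invisible(x)
}

#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults: the 0.53-60 Hz
#' zero-phase band-pass, 16 windows per record, 64-sample sub-segments at 75%
#' overlap for the HOS estimates, standard clinical bands, both selectors
#' combined by intersection, and a Gaussian-kernel LS-SVM.
#'
#' @param fs sampling rate in Hz.
#' @param low_cut,high_cut,filter_order band-pass settings.
#' @param n_windows analysis windows per record.
#' @param seg_len,overlap HOS sub-segmentation within each window.
#' @param bands a [band_scheme].
#' @param selection `"both"` (GA and t-ranking combined), `"ttest"`, `"ga"`,
#'   or `"none"`.
#' @param combine how GA and t-ranked sets merge when `selection = "both"`:
#'   `"intersection"` (default), `"union"`, `"ga_only"`.
#' @param alpha t-ranking pass threshold.
#' @param ga a [ga_config] for the wrapper search.
#' @param coding `"ovo"` or `"ecoc"`.
#' @param kernel `"gaussian"` or `"polynomial"`.
#' @param gamma LS-SVM regularization.
#' @param sigma Gaussian bandwidth; `NULL` means `sqrt(d)` for `d` selected
#'   features.
#' @param degree,offset polynomial kernel settings.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fs = 173.61, low_cut = 0.53, high_cut = 60,
                            filter_order = 4L, n_windows = 16L,
                            seg_len = 64L, overlap = 0.75,
                            bands = band_scheme(),
                            selection = c("both", "ttest", "ga", "none"),
                            combine = c("intersection", "union", "ga_only"),
                            alpha = 0.001,
                            ga = ga_config(population_size = 20L,
                                           generations = 25L),
                            coding = c("ovo", "ecoc"),
                            kernel = c("gaussian", "polynomial"),
                            gamma = 10, sigma = NULL, degree = 2L, offset = 1) {
  structure(list(fs = fs, low_cut = low_cut, high_cut = high_cut,
                 filter_order = as.integer(filter_order),
                 n_windows = as.integer(n_windows),
                 seg_len = as.integer(seg_len), overlap = overlap,
                 bands = bands, selection = match.arg(selection),
                 combine = match.arg(combine), alpha = alpha, ga = ga,
                 coding = match.arg(coding), kernel = match.arg(kernel),
                 gamma = gamma, sigma = sigma, degree = as.integer(degree),
                 offset = offset),
            class = "pipeline_config")
}

#' Extract per-window feature vectors from a Bonn-layout directory
#'
#' Reads every manifest record, band-pass filters it, cuts it into windows,
#' and computes the 47 HOS features per window.
#'
#' @param data_dir dataset root (per-set subdirectories + `manifest.csv`).
#' @param config a [pipeline_config].
#' @param manifest optional manifest data.frame (`file`, `set`, `class`);
#'   read from `data_dir/manifest.csv` by default.
#' @param sets restrict to these set ids (default: all in the manifest).
#' @return list with feature matrix `X` (one row per window), `meta`
#'   data.frame (`set`, `record`, `window`).
#' @export
dataset_features <- function(data_dir, config = pipeline_config(),
                             manifest = NULL, sets = NULL) {
  if (is.null(manifest)) {
    mpath <- file.path(data_dir, "manifest.csv")
    if (!file.exists(mpath)) stop_hos("no manifest.csv under ", data_dir)
    manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  }
  if (!is.null(sets)) manifest <- manifest[manifest$set %in% sets, ]
  if (nrow(manifest) == 0L) {
    stop_hos("no records to read; expected sets: ",
             paste(sets %||% "any", collapse = ", "))
  }
  fspec <- filter_spec(config$low_cut, config$high_cut, config$filter_order)
  grid <- bifrequency_grid(config$seg_len, config$fs)
  regions <- build_regions(config$bands, principal_domain(grid))
  rows <- vector("list", nrow(manifest) * config$n_windows)
  meta <- vector("list", length(rows))
  r <- 0L
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(data_dir, manifest$file[i])
    rec <- read_bonn_record(path, fs = config$fs, set_id = manifest$set[i])
    rec <- bandpass_zero_phase(rec, fspec)
    for (w in window_record(rec, config$n_windows)) {
      r <- r + 1L
      rows[[r]] <- window_features(w, fs = config$fs,
                                   seg_len = config$seg_len,
                                   overlap = config$overlap,
                                   regions = regions)
      meta[[r]] <- data.frame(set = manifest$set[i], record = rec$record_id,
                              window = w$index, stringsAsFactors = FALSE)
    }
  }
  list(X = do.call(rbind, rows), meta = do.call(rbind, meta))
}

#' Run one end-to-end classification experiment
#'
#' Executes the full chain on a Bonn-layout dataset: read, zero-phase filter,
#' window, HOS feature extraction (47 features per window), train-fitted
#' z-score normalization, feature selection (t-ranking and/or GA wrapper),
#' LS-SVM training, and evaluation on the held-out test partition. No test
#' vector influences normalization, selection or hyperparameters; GA fitness
#' is scored on the validation partition only.
#'
#' @param data_dir dataset root with `manifest.csv`.
#' @param spec an [experiment_spec].
#' @param config a [pipeline_config].
#' @param use_ga run the GA selector (set `FALSE` for the without-GA
#'   ablation).
#' @return object of class `hos_experiment` with the test `metrics`,
#'   confusion counts, the selection tables and mask, split counts, and the
#'   fitted model.
#' @export
run_experiment <- function(data_dir, spec = experiment_spec(1L),
                           config = pipeline_config(), use_ga = TRUE) {
  feats <- dataset_features(data_dir, config, sets = names(spec$set_class))
  missing_sets <- setdiff(names(spec$set_class), unique(feats$meta$set))
  if (length(missing_sets))
    stop_hos("dataset lacks required set(s): ", paste(missing_sets, collapse = ", "))
  y <- factor(unname(spec$set_class[feats$meta$set]))
  X <- feats$X

  split <- make_split(table(y), spec)
  part <- character(length(y))
  for (cl in names(split$assignment)) part[y == cl] <- split$assignment[[cl]]
  tr <- part == "train"; va <- part == "validation"; te <- part == "test"

  norm <- fit_normalizer(X[tr, , drop = FALSE])
  Ztr <- apply_normalizer(norm, X[tr, , drop = FALSE])
  Zva <- apply_normalizer(norm, X[va, , drop = FALSE])
  Zte <- apply_normalizer(norm, X[te, , drop = FALSE])

  sel <- select_features(Ztr, y[tr], Zva, y[va], config,
                         use_ga = use_ga, seed = spec$seed)
  mask <- sel$mask
  if (!any(mask)) mask <- rep(TRUE, ncol(Ztr))

  kern <- make_kernel(config, d = sum(mask))
  k <- nlevels(y)
  model <- if (k == 2L)
    lssvm(Ztr[, mask, drop = FALSE], y[tr], config$gamma, kern)
  else
    lssvm_multiclass(Ztr[, mask, drop = FALSE], y[tr], config$coding,
                     config$gamma, kern,
                     seed = derive_seed(spec$seed, "ecoc"))
  pred <- predict(model, Zte[, mask, drop = FALSE])
  counts <- confusion_counts(y[te], pred)
  structure(list(metrics = compute_metrics(counts), confusion = counts,
                 selection = sel, mask = mask,
                 feature_names = colnames(Ztr),
                 split_counts = split$counts, normalizer = norm,
                 model = model, spec = spec, config = config,
                 n_vectors = nrow(X)),
            class = "hos_experiment")
}

make_kernel <- function(config, d) {
  if (config$kernel == "gaussian")
    kernel_spec("gaussian", sigma = config$sigma %||% sqrt(d))
  else
    kernel_spec("polynomial", degree = config$degree, offset = config$offset)
}

# Combine t-ranking and GA-wrapper masks per the configured policy.
select_features <- function(Ztr, ytr, Zva, yva, config, use_ga, seed) {
  d <- ncol(Ztr)
  nm <- colnames(Ztr)
  method <- config$selection
  if (!use_ga && method %in% c("both", "ga")) {
    method <- if (method == "both") "ttest" else "none"
  }
  rank_tab <- NULL
  t_mask <- rep(TRUE, d)
  if (method %in% c("both", "ttest")) {
    rank_tab <- rank_multiclass(Ztr, ytr, config$alpha)
    t_mask <- nm %in% rank_tab$feature[rank_tab$pass]
  }
  ga_res <- NULL
  ga_mask <- rep(TRUE, d)
  if (method %in% c("both", "ga")) {
    fitness <- make_lssvm_fitness(Ztr, ytr, Zva, yva, gamma = config$gamma,
                                  kernel = make_kernel(config, d),
                                  coding = config$coding)
    cfg <- config$ga
    cfg$seed <- derive_seed(seed, "ga")
    ga_res <- ga_search(d, fitness, cfg)
    ga_mask <- ga_res$mask
  }
  mask <- switch(method,
    none = rep(TRUE, d),
    ttest = t_mask,
    ga = ga_mask,
    both = switch(config$combine,
                  intersection = {
                    m <- t_mask & ga_mask
                    if (!any(m)) t_mask | ga_mask else m  # fall back to union
                  },
                  union = t_mask | ga_mask,
                  ga_only = ga_mask)
  )
  list(mask = mask, method = method, ranking = rank_tab, ga = ga_res,
       t_mask = t_mask, ga_mask = ga_mask)
}

# Multiclass extension of the binary ranking: a feature's p-value is its
# best (minimum) two-class p over all class pairs.
rank_multiclass <- function(X, y, alpha) {
  f <- factor(y)
  if (nlevels(f) == 2L) return(ttest_rank(X, f, alpha))
  pairs <- utils::combn(levels(f), 2L)
  pmin_ <- rep(1, ncol(X))
  tbest <- rep(0, ncol(X))
  for (c in seq_len(ncol(pairs))) {
    sel <- f %in% pairs[, c]
    r <- ttest_rank(X[sel, , drop = FALSE], droplevels(f[sel]), alpha)
    r <- r[match(colnames(X) %||% paste0("f", seq_len(ncol(X))), r$feature), ]
    upd <- r$p < pmin_
    pmin_[upd] <- r$p[upd]
    tbest[upd] <- r$t[upd]
  }
  nm <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  out <- data.frame(feature = nm, t = tbest, p = pmin_, pass = pmin_ < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  attr(out, "alpha") <- alpha
  class(out) <- c("rank_result", "data.frame")
  out
}

#' @export
print.hos_experiment <- function(x, ...) {
  cat(sprintf("<hos_experiment> #%s: %s\n",
              x$spec$id %||% "custom",
              paste(sprintf("%s=%s", names(x$spec$set_class),
                            x$spec$set_class), collapse = " ")))
  cat(sprintf("  %d feature vectors; %d/%d features selected (%s)\n",
              x$n_vectors, sum(x$mask), length(x$mask),
              x$selection$method))
  print(x$metrics)
  invisible(x)
}
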