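## Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the caller's
# RNG state afterwards. All seeded operations in the package go through this so
# user code is never perturbed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline (synthetic generation, splitting,
#' genetic search, code-matrix construction) draws its seed deterministically
#' from one master seed, so a single integer reproduces a whole run.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  # cheap string hash; stable across platforms
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 7919 + h * 104729) %% .Machine$integer.max)
}

stop_hos <- function(...) stop(..., call. = FALSE)

# Coerce segment containers (matrix with segments in columns, list of numeric
# vectors, list of eeg_window objects, or a single vector) to a numeric matrix.
as_segment_matrix <- function(windows) {
  if (is.matrix(windows)) {
    storage.mode(windows) <- "double"
    return(windows)
  }
  if (is.numeric(windows)) return(matrix(as.double(windows), ncol = 1L))
  if (is.list(windows)) {
    if (length(windows) == 0L) stop_hos("empty window list")
    vecs <- lapply(windows, function(w) {
      if (inherits(w, "eeg_window")) as.double(w$samples) else as.double(w)
    })
    len <- unique(vapply(vecs, length, 1L))
    if (length(len) != 1L) stop_hos("all segments must share one length")
    return(matrix(unlist(vecs), nrow = len))
  }
  stop_hos("cannot interpret 'windows' as segments")
}
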