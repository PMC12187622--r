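# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
#' caller's RNG afterwards so library calls never disturb user-level streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed < 2^31 from a parent seed and a stream label
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

# locale-independent lexicographic sort (C collation)
sort_c <- function(x) sort(x, method = "radix")

is_missing_value <- function(x) is.na(x) | x == "-"

#' Stratified k-fold assignment
#'
#' Assigns each observation to one of `k` folds so that within every class the
#' fold sizes differ by at most one observation.
#'
#' @param labels factor or character vector of class labels.
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, same length as `labels`.
#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort_c(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}
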