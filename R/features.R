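# Feature engineering: sanitised per-series metadata -> numeric design matrix
# (word n-gram counts + numeric-string summaries) or raw categorical
# pass-through for the native-categorical learner.

NUMERIC_SUMMARY_STATS <- c("n_chars", "sum", "mean", "min", "max")

#' Infer per-field column typing
#'
#' A field is \code{numeric-string} iff every non-missing value parses
#' entirely as whitespace-separated decimal numbers; otherwise (including
#' all-missing fields) it is \code{categorical}.
#'
#' @param records list of \code{mrseries_record}.
#' @return named character vector, field name -> \code{"categorical"} or
#'   \code{"numeric-string"}.
#' @export
infer_column_typing <- function(records) {
  stopifnot(length(records) >= 1L)
  fields <- names(records[[1]]$fields)
  out <- vapply(fields, function(f) {
    vals <- vapply(records, function(r) r$fields[[f]] %||% "-", character(1))
    vals <- vals[vals != "-"]
    if (length(vals) == 0L) return("categorical")
    ok <- vapply(vals, function(v) {
      toks <- strsplit(v, " ", fixed = TRUE)[[1]]
      length(toks) > 0L && !anyNA(suppressWarnings(as.numeric(toks)))
    }, logical(1))
    if (all(ok)) "numeric-string" else "categorical"
  }, character(1))
  out
}

# contiguous word n-grams of value (a sanitised string); counts per n-gram.
# Metadata values recur across series and CV folds, so results are memoised.
.ngram_cache <- new.env(parent = emptyenv())

ngram_counts <- function(value, ngram_range) {
  if (is_missing_value(value)) return(integer(0))
  key <- paste(ngram_range[1], ngram_range[2], value, sep = "\r")
  hit <- get0(key, envir = .ngram_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  words <- strsplit(value, " ", fixed = TRUE)[[1]]
  nw <- length(words)
  grams <- character(0)
  for (n in ngram_range[1]:ngram_range[2]) {
    if (n > nw) break
    idx <- seq_len(nw - n + 1L)
    grams <- c(grams, vapply(idx, function(i)
      paste(words[i:(i + n - 1L)], collapse = " "), character(1)))
  }
  res <- if (length(grams) == 0L) integer(0) else {
    u <- unique(grams)
    stats::setNames(tabulate(match(grams, u), length(u)), u)
  }
  assign(key, res, envir = .ngram_cache)
  res
}

#' Build a token vocabulary for one categorical field
#'
#' Tokens are contiguous word n-grams (space-delimited words, sizes from
#' \code{ngram_range}) over each series' value. The document frequency of a
#' token is the fraction of series whose value contains it at least once;
#' tokens below \code{min_df} are dropped. Missing values (\code{"-"})
#' contribute no tokens but count in the denominator.
#'
#' @param records list of \code{mrseries_record}.
#' @param field field name.
#' @param min_df minimum document frequency in (0, 1], default 0.01 (a token
#'   must appear in at least 1\% of series).
#' @param ngram_range integer pair (min, max) n-gram size, default \code{c(1, 5)}.
#' @return object of class \code{mrseries_vocab}: list with \code{tokens}
#'   (lexicographically ordered), \code{document_frequency}, \code{min_df},
#'   \code{ngram_range}, \code{source_field}.
#' @export
build_vocabulary <- function(records, field, min_df = 0.01, ngram_range = c(1L, 5L)) {
  stopifnot(length(records) >= 1L, min_df > 0, min_df <= 1)
  values <- vapply(records, function(r) r$fields[[field]] %||% "-", character(1))
  n <- length(values)
  # metadata values repeat heavily: tokenise each distinct value once and
  # weight by its number of occurrences
  val_tab <- table(values)
  gram_lists <- lapply(names(val_tab), function(v) names(ngram_counts(v, ngram_range)))
  if (sum(lengths(gram_lists)) == 0L) {   # e.g. an all-missing field
    counts <- integer(0); toks <- character(0)
  } else {
    counts <- tapply(rep(as.integer(val_tab), lengths(gram_lists)),
                     unlist(gram_lists), sum)
    toks <- names(counts)
  }
  df <- as.numeric(counts) / n
  keep <- if (length(toks) > 0L) df >= min_df else logical(0)
  ord <- order(toks[keep], method = "radix")
  structure(list(tokens = toks[keep][ord],
                 document_frequency = stats::setNames(df[keep][ord], toks[keep][ord]),
                 min_df = min_df, ngram_range = as.integer(ngram_range),
                 source_field = field),
            class = "mrseries_vocab")
}

#' Summarise a space-separated numeric string
#'
#' @param value sanitised string, e.g. \code{"1.0 2.0 4.0"}.
#' @return named numeric vector \code{(n_chars, sum, mean, min, max)}:
#'   \code{n_chars} is the character count of the full string (spaces
#'   included); the other four are computed over the parsed numbers.
#'   \code{"-"} yields all-\code{NA}; tokens that fail to parse are dropped
#'   from the four statistics.
#' @examples
#' summarise_numeric_string("1.0 2.0 4.0")  # 11, 7, 2.333, 1, 4
#' @export
summarise_numeric_string <- function(value) {
  out <- stats::setNames(rep(NA_real_, 5L), NUMERIC_SUMMARY_STATS)
  if (length(value) != 1L || is_missing_value(value)) return(out)
  out["n_chars"] <- nchar(value)
  nums <- suppressWarnings(as.numeric(strsplit(value, " ", fixed = TRUE)[[1]]))
  nums <- nums[!is.na(nums)]
  if (length(nums) > 0L) {
    out["sum"] <- sum(nums); out["mean"] <- mean(nums)
    out["min"] <- min(nums); out["max"] <- max(nums)
  }
  out
}

# rowwise numeric summaries, computed once per distinct value
summarise_numeric_values <- function(vals) {
  uv <- unique(vals)
  um <- t(vapply(uv, summarise_numeric_string, numeric(5L)))
  m <- um[match(vals, uv), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# fields removed by each feature-set variant
variant_drop_fields <- function(variant) {
  switch(variant,
    all = character(0),
    no_sd = "SeriesDescription",
    no_fov_sar = c("PercentPhaseFieldOfView", "SAR"),
    no_sd_fov_sar = c("SeriesDescription", "PercentPhaseFieldOfView", "SAR"),
    stop("unknown feature-set variant: ", variant))
}

# fields used for model features (identifiers and private b-value tags are
# curation inputs, not predictors of the classifier design matrix)
model_fields <- function(typing, variant) {
  drop <- c(variant_drop_fields(variant), "SeriesNumber",
            "PrivateBValueGE", "PrivateBValueSiemens")
  setdiff(names(typing), drop)
}

#' Build the engineered feature matrix
#'
#' Categorical fields expand to per-field token-count columns (counts of each
#' vocabulary n-gram in the value); numeric-string fields expand to the five
#' summary statistics. Tokens unseen at vocabulary-build time are ignored, so
#' test-set vectorization never adds columns.
#'
#' @param records list of \code{mrseries_record}.
#' @param typing from [infer_column_typing()] (built on training data).
#' @param vocabularies named list of [build_vocabulary()] results, one per
#'   categorical field (built on training data).
#' @param variant feature-set variant, see [default_tag_config()].
#' @return object of class \code{mrseries_features}: list with \code{x}
#'   (numeric matrix, NA allowed), \code{provenance} (data.frame: column,
#'   kind, field), \code{series_uids}.
#' @export
vectorize <- function(records, typing, vocabularies, variant = "all") {
  fields <- model_fields(typing, variant)
  miss <- setdiff(fields[typing[fields] == "categorical"], names(vocabularies))
  if (length(miss) > 0L)
    stop("no vocabulary for categorical field(s): ", paste(miss, collapse = ", "))
  blocks <- list()
  prov <- list()
  for (f in fields) {
    vals <- vapply(records, function(r) r$fields[[f]] %||% "-", character(1))
    if (typing[[f]] == "categorical") {
      vocab <- vocabularies[[f]]
      if (length(vocab$tokens) == 0L) next
      m <- matrix(0, nrow = length(records), ncol = length(vocab$tokens),
                  dimnames = list(NULL, paste0("tok:", f, ":", vocab$tokens)))
      # tokenise each distinct value once, then scatter to its rows
      rows_by_val <- split(seq_along(vals), vals)
      for (v in names(rows_by_val)) {
        cnt <- ngram_counts(v, vocab$ngram_range)
        pos <- match(names(cnt), vocab$tokens)
        hit <- which(!is.na(pos))
        if (length(hit) > 0L)
          m[rows_by_val[[v]], pos[hit]] <-
            matrix(cnt[hit], nrow = length(rows_by_val[[v]]),
                   ncol = length(hit), byrow = TRUE)
      }
      blocks[[length(blocks) + 1L]] <- m
      prov[[length(prov) + 1L]] <- data.frame(column = colnames(m),
                                              kind = "token", field = f)
    } else {
      m <- summarise_numeric_values(vals)
      colnames(m) <- paste0("num:", f, ":", NUMERIC_SUMMARY_STATS)
      blocks[[length(blocks) + 1L]] <- m
      prov[[length(prov) + 1L]] <- data.frame(column = colnames(m),
                                              kind = "numeric-summary", field = f)
    }
  }
  x <- do.call(cbind, blocks)
  structure(list(x = x, provenance = do.call(rbind, prov),
                 series_uids = vapply(records, `[[`, character(1), "series_uid")),
            class = "mrseries_features")
}

#' Build the raw-categorical pass-through frame
#'
#' For the native-categorical backend: categorical fields are passed as factor
#' columns (no explicit tokenization — the learner handles categories
#' internally); numeric-string fields are still summarised into the five
#' statistics. Missing values become \code{NA}.
#'
#' @inheritParams vectorize
#' @param levels optional named list of factor levels per categorical field
#'   (from training); values outside them become \code{NA} at prediction time.
#' @return object of class \code{mrseries_features_raw}: list with \code{x}
#'   (data.frame with factor + numeric columns), \code{levels},
#'   \code{series_uids}.
#' @export
passthrough_categorical <- function(records, typing, variant = "all", levels = NULL) {
  fields <- model_fields(typing, variant)
  cols <- list()
  out_levels <- list()
  for (f in fields) {
    vals <- vapply(records, function(r) r$fields[[f]] %||% "-", character(1))
    if (typing[[f]] == "categorical") {
      vals[vals == "-"] <- NA_character_
      lv <- if (!is.null(levels)) levels[[f]] else sort_c(unique(vals[!is.na(vals)]))
      cols[[paste0("cat:", f)]] <- factor(vals, levels = lv)
      out_levels[[f]] <- lv
    } else {
      m <- summarise_numeric_values(vals)
      colnames(m) <- NUMERIC_SUMMARY_STATS
      for (s in NUMERIC_SUMMARY_STATS) cols[[paste0("num:", f, ":", s)]] <- m[, s]
    }
  }
  x <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(x = x, levels = out_levels,
                 series_uids = vapply(records, `[[`, character(1), "series_uid")),
            class = "mrseries_features_raw")
}

#' Serialise a vocabulary to JSON
#'
#' @param vocab an \code{mrseries_vocab}.
#' @param path output path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(source_field = vocab$source_field, min_df = vocab$min_df,
         ngram_range = vocab$ngram_range,
         tokens = data.frame(token = vocab$tokens,
                             df = as.numeric(vocab$document_frequency))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
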