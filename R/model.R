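# Five-class gradient-boosted series-type classifiers: engineered token-count
# features or native categorical handling, nested stratified CV with random
# hyperparameter search.

#' Fixed label map
#'
#' Class order is fixed so encodings and confusion matrices are comparable
#' across runs.
#'
#' @return character vector \code{c("T2W","DWI","ADC","DCE","OTHERS")}.
#' @export
series_classes <- function() SERIES_CLASSES

#' Default random-search hyperparameter grid
#'
#' Standard gradient-boosting ranges; candidates are drawn uniformly with
#' replacement from the Cartesian product.
#'
#' @param n_iterations number of random draws per search (default 50).
#' @return object of class \code{mrseries_grid}.
#' @export
default_grid <- function(n_iterations = 50L) {
  hyper_grid(max_depth = c(4L, 6L, 8L, 10L),
             learning_rate = c(0.03, 0.1, 0.3),
             nrounds = c(100L, 300L, 600L),
             subsample = c(0.7, 1.0),
             colsample_bytree = c(0.7, 1.0),
             reg_lambda = c(1, 3, 10),
             n_iterations = n_iterations)
}

#' Build a hyperparameter grid
#'
#' @param max_depth,learning_rate,nrounds,subsample,colsample_bytree,reg_lambda
#'   candidate values (non-empty numeric vectors).
#' @param n_iterations number of random-search draws.
#' @return object of class \code{mrseries_grid}.
#' @export
hyper_grid <- function(max_depth = 6L, learning_rate = 0.3, nrounds = 100L,
                       subsample = 1.0, colsample_bytree = 1.0, reg_lambda = 1,
                       n_iterations = 10L) {
  params <- list(max_depth = max_depth, learning_rate = learning_rate,
                 nrounds = nrounds, subsample = subsample,
                 colsample_bytree = colsample_bytree, reg_lambda = reg_lambda)
  if (any(vapply(params, length, 0L) == 0L)) stop("empty candidate list")
  structure(list(params = params, n_iterations = as.integer(n_iterations)),
            class = "mrseries_grid")
}

# draw n candidate parameter sets, uniformly with replacement per dimension
sample_grid <- function(grid, n, seed) {
  with_seed(seed, {
    lapply(seq_len(n), function(i)
      lapply(grid$params, function(v) v[[sample.int(length(v), 1L)]]))
  })
}

# candidate preference for ties: fewer trees, then shallower
candidate_order <- function(scores, candidates) {
  nr <- vapply(candidates, function(p) p$nrounds, 0)
  md <- vapply(candidates, function(p) p$max_depth, 0)
  order(-scores, nr, md)
}

check_labels <- function(labels) {
  missing_cl <- setdiff(SERIES_CLASSES, unique(labels))
  if (length(missing_cl) > 0L)
    stop("class(es) absent from the data: ", paste(missing_cl, collapse = ", "))
  if (length(unique(labels)) < 2L) stop("degenerate single-class data")
}

# ---- preprocessing ---------------------------------------------------------

build_preprocessing <- function(train_records, backend, variant,
                                min_df = 0.01, ngram_range = c(1L, 5L)) {
  typing <- infer_column_typing(train_records)
  if (backend == "engineered") {
    cat_fields <- model_fields(typing, variant)
    cat_fields <- cat_fields[typing[cat_fields] == "categorical"]
    vocabs <- lapply(cat_fields, function(f)
      build_vocabulary(train_records, f, min_df = min_df, ngram_range = ngram_range))
    names(vocabs) <- cat_fields
    list(backend = backend, variant = variant, typing = typing,
         vocabularies = vocabs, min_df = min_df, ngram_range = ngram_range)
  } else {
    ft <- passthrough_categorical(train_records, typing, variant)
    list(backend = backend, variant = variant, typing = typing,
         levels = ft$levels)
  }
}

featurise <- function(records, prep) {
  if (prep$backend == "engineered") {
    vectorize(records, prep$typing, prep$vocabularies, prep$variant)$x
  } else {
    passthrough_categorical(records, prep$typing, prep$variant,
                            levels = prep$levels)$x
  }
}

fit_booster <- function(x, y, params, seed) {
  xgboost::xgboost(
    x, y,
    nrounds = params$nrounds, max_depth = params$max_depth,
    learning_rate = params$learning_rate, subsample = params$subsample,
    colsample_bytree = params$colsample_bytree, reg_lambda = params$reg_lambda,
    nthreads = 1L, verbosity = 0L, seed = as.integer(seed %% 2147483647))
}

predict_probs <- function(model, x) {
  p <- predict(model, x, type = "response")
  p[, SERIES_CLASSES, drop = FALSE]
}

# ---- nested cross-validation ----------------------------------------------

#' Train a series-type classifier with nested cross-validation
#'
#' Outer loop: stratified \code{outer_k}-fold split giving an unbiased
#' performance estimate. Inner loop, per outer training split:
#' \code{grid$n_iterations} random candidates, each scored by stratified
#' \code{inner_k}-fold CV macro F1 (preprocessing rebuilt on each inner
#' training split so the held-out rows never leak into vocabularies); ties
#' broken towards fewer trees, then lower depth. The final model is refit on
#' all records with the best overall candidate.
#'
#' @param records list of labelled \code{mrseries_record} (each with a
#'   \code{label} in [series_classes()]).
#' @param backend \code{"engineered"} (token-count features) or
#'   \code{"native-categorical"} (factor columns handled inside the learner).
#' @param variant feature-set variant, see [default_tag_config()].
#' @param grid a [hyper_grid()]; default [default_grid()].
#' @param outer_k,inner_k fold counts (default 5/5).
#' @param seed integer; all randomness (folds, candidate draws, learner) flows
#'   from it.
#' @param min_df,ngram_range vocabulary parameters for the engineered backend.
#' @return list with \code{bundle} (a model bundle usable with
#'   [predict_series()]) and \code{report} (outer-loop [score()] report with
#'   per-fold breakdowns and chosen hyperparameters).
#' @export
nested_cv_train <- function(records, backend = c("engineered", "native-categorical"),
                            variant = "all", grid = default_grid(),
                            outer_k = 5L, inner_k = 5L, seed = 1L,
                            min_df = 0.01, ngram_range = c(1L, 5L)) {
  backend <- match.arg(backend)
  labels <- vapply(records, function(r) r$label %||% NA_character_, character(1))
  if (anyNA(labels)) stop("all records must carry a label")
  check_labels(labels)
  outer_folds <- stratified_folds(labels, outer_k, child_seed(seed, "outer"))

  fold_results <- vector("list", outer_k)
  all_pred <- character(length(records))
  for (ko in seq_len(outer_k)) {
    tr_idx <- which(outer_folds != ko)
    te_idx <- which(outer_folds == ko)
    search <- random_search(records[tr_idx], labels[tr_idx], backend, variant,
                            grid, inner_k, child_seed(seed, paste0("inner", ko)),
                            min_df, ngram_range)
    prep <- build_preprocessing(records[tr_idx], backend, variant, min_df, ngram_range)
    model <- fit_booster(featurise(records[tr_idx], prep),
                         factor(labels[tr_idx], levels = SERIES_CLASSES),
                         search$best, child_seed(seed, paste0("outerfit", ko)))
    probs <- predict_probs(model, featurise(records[te_idx], prep))
    pred <- SERIES_CLASSES[max.col(probs, ties.method = "first")]
    all_pred[te_idx] <- pred
    fold_results[[ko]] <- list(fold = ko, test_idx = te_idx,
                               train_fingerprint = sum(te_idx) * 1e-6 + length(tr_idx),
                               best = search$best, best_inner_score = search$best_score,
                               report = score(labels[te_idx], pred))
  }

  inner_scores <- vapply(fold_results, `[[`, 0, "best_inner_score")
  best_cands <- lapply(fold_results, `[[`, "best")
  best_overall <- best_cands[[candidate_order(inner_scores, best_cands)[1L]]]

  prep_full <- build_preprocessing(records, backend, variant, min_df, ngram_range)
  final <- fit_booster(featurise(records, prep_full),
                       factor(labels, levels = SERIES_CLASSES),
                       best_overall, child_seed(seed, "final"))

  report <- score(labels, all_pred)
  report$per_fold <- lapply(fold_results, function(fr)
    list(fold = fr$fold, chosen = fr$best, inner_macro_f1 = fr$best_inner_score,
         per_class = fr$report$per_class, macro_f1 = fr$report$macro_f1))

  bundle <- structure(list(
    schema_version = 1L, backend = backend, variant = variant,
    preprocessing = prep_full, model = final,
    label_map = stats::setNames(0:4, SERIES_CLASSES),
    manifest = list(seed = seed, hyperparameters = best_overall,
                    outer_macro_f1 = report$macro_f1,
                    n_records = length(records),
                    data_fingerprint = sum(utf8ToInt(paste(
                      vapply(records[1:min(5, length(records))], `[[`,
                             character(1), "series_uid"), collapse = ""))))),
    class = "mrseries_bundle")
  list(bundle = bundle, report = report)
}

# random hyperparameter search scored by stratified inner CV macro F1;
# feature preprocessing is built once per inner fold and shared by candidates
random_search <- function(train_records, train_labels, backend, variant, grid,
                          inner_k, seed, min_df, ngram_range) {
  candidates <- sample_grid(grid, grid$n_iterations, child_seed(seed, "draw"))
  folds <- stratified_folds(train_labels, inner_k, child_seed(seed, "folds"))
  prepared <- lapply(seq_len(inner_k), function(ki) {
    tr <- which(folds != ki); te <- which(folds == ki)
    prep <- build_preprocessing(train_records[tr], backend, variant, min_df, ngram_range)
    list(xtr = featurise(train_records[tr], prep),
         ytr = factor(train_labels[tr], levels = SERIES_CLASSES),
         xte = featurise(train_records[te], prep),
         yte = train_labels[te])
  })
  scores <- vapply(seq_along(candidates), function(ci) {
    f1 <- vapply(prepared, function(pp) {
      m <- fit_booster(pp$xtr, pp$ytr, candidates[[ci]],
                       child_seed(seed, paste0("fit", ci)))
      pred <- SERIES_CLASSES[max.col(predict_probs(m, pp$xte), ties.method = "first")]
      score(pp$yte, pred)$macro_f1
    }, 0)
    mean(f1)
  }, 0)
  best_i <- candidate_order(scores, candidates)[1L]
  list(best = candidates[[best_i]], best_score = scores[best_i],
       all = data.frame(candidate = seq_along(candidates), macro_f1 = scores))
}

#' Predict series types
#'
#' @param bundle a model bundle from [nested_cv_train()] (or [load_bundle()]).
#' @param records list of \code{mrseries_record}.
#' @return data.frame with \code{series_uid}, \code{predicted_label}, one
#'   probability column per class (\code{p_T2W} ... \code{p_OTHERS}; rows sum
#'   to 1), and \code{low_confidence} (TRUE when every configured field of the
#'   record was missing).
#' @export
predict_series <- function(bundle, records) {
  stopifnot(inherits(bundle, "mrseries_bundle"))
  probs <- predict_probs(bundle$model, featurise(records, bundle$preprocessing))
  pred <- SERIES_CLASSES[max.col(probs, ties.method = "first")]
  all_missing <- vapply(records, function(r)
    all(vapply(r$fields, function(v) is_missing_value(v), logical(1))), logical(1))
  out <- data.frame(series_uid = vapply(records, `[[`, character(1), "series_uid"),
                    predicted_label = pred, stringsAsFactors = FALSE)
  colnames(probs) <- paste0("p_", SERIES_CLASSES)
  cbind(out, as.data.frame(probs), low_confidence = all_missing)
}

#' Save / load a model bundle
#'
#' The bundle embeds a schema version; loading a file with a different schema
#' (or a non-bundle file) fails explicitly. A save/load round trip preserves
#' predictions exactly.
#'
#' @param bundle a model bundle.
#' @param path file path.
#' @return \code{save_bundle}: \code{path}, invisibly. \code{load_bundle}: the
#'   bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "mrseries_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model bundle from ", path, ": ", conditionMessage(e)))
  if (!inherits(obj, "mrseries_bundle"))
    stop("file is not an mrseries model bundle: ", path)
  if (!identical(obj$schema_version, 1L))
    stop("unsupported bundle schema version: ", obj$schema_version)
  obj
}
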