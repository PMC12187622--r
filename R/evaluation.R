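# Metrics, leave-one-centre-out cross-validation, learning curves and the
# two-step saturation detector.

#' Score predictions against ground truth
#'
#' One-vs-rest precision, recall and F1 per class; macro F1 is the unweighted
#' mean over the five classes (weighted mean also reported); confusion matrix
#' rows are the true class, columns the predicted class, in fixed class order.
#' F1 is defined as 0 when precision and recall are both 0.
#'
#' @param true_labels,predicted_labels character vectors of equal length with
#'   values in [series_classes()].
#' @return object of class \code{mrseries_eval}: list with \code{per_class}
#'   (data.frame: class, precision, recall, f1, support), \code{macro_f1},
#'   \code{weighted_f1}, \code{confusion} (5x5 integer matrix), \code{n}.
#' @export
score <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), SERIES_CLASSES)
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tf <- factor(true_labels, levels = SERIES_CLASSES)
  pf <- factor(predicted_labels, levels = SERIES_CLASSES)
  confusion <- table(true = tf, predicted = pf)
  per_class <- do.call(rbind, lapply(SERIES_CLASSES, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               support = tp + fn, stringsAsFactors = FALSE)
  }))
  support <- per_class$support
  weighted_f1 <- if (sum(support) == 0) 0 else sum(per_class$f1 * support) / sum(support)
  structure(list(per_class = per_class, macro_f1 = mean(per_class$f1),
                 weighted_f1 = weighted_f1,
                 confusion = unclass(confusion), n = length(true_labels)),
            class = "mrseries_eval")
}

#' @export
print.mrseries_eval <- function(x, ...) {
  cat("series-type evaluation on", x$n, "series\n")
  print(transform(x$per_class, precision = round(precision, 4),
                  recall = round(recall, 4), f1 = round(f1, 4)), row.names = FALSE)
  cat(sprintf("macro F1 %.4f | weighted F1 %.4f\n", x$macro_f1, x$weighted_f1))
  invisible(x)
}

#' Leave-one-centre-out cross-validation
#'
#' One fold per centre: the model is trained (with its own random
#' hyperparameter search, so the held-out centre never influences selection)
#' on all other centres and scored on the held-out centre. Per-class F1
#' deltas versus pooled stratified 5-fold CV on the same records and seed are
#' returned — negative deltas mean the centre is harder to classify unseen.
#'
#' @inheritParams nested_cv_train
#' @param inner_k folds of the per-fold hyperparameter search.
#' @return list with \code{per_group} (centre -> \code{mrseries_eval}),
#'   \code{pooled} (pooled-CV \code{mrseries_eval}),
#'   \code{delta_vs_pooled_cv} (centre -> named per-class F1 difference) and
#'   \code{macro_delta} (centre -> macro F1 difference).
#' @export
logocv <- function(records, backend = c("engineered", "native-categorical"),
                   variant = "all", grid = default_grid(), seed = 1L,
                   inner_k = 5L, min_df = 0.01, ngram_range = c(1L, 5L)) {
  backend <- match.arg(backend)
  labels <- vapply(records, function(r) r$label %||% NA_character_, character(1))
  check_labels(labels)
  centres <- vapply(records, function(r) r$centre_id %||% NA_character_, character(1))
  if (anyNA(centres)) stop("all records must carry a centre_id")
  groups <- sort_c(unique(centres))
  if (length(groups) < 2L) stop("leave-one-centre-out needs >= 2 centres")

  per_group <- list()
  for (g in groups) {
    tr <- which(centres != g); te <- which(centres == g)
    search <- random_search(records[tr], labels[tr], backend, variant, grid,
                            inner_k, child_seed(seed, paste0("logo_", g)),
                            min_df, ngram_range)
    prep <- build_preprocessing(records[tr], backend, variant, min_df, ngram_range)
    model <- fit_booster(featurise(records[tr], prep),
                         factor(labels[tr], levels = SERIES_CLASSES),
                         search$best, child_seed(seed, paste0("logofit_", g)))
    pred <- SERIES_CLASSES[max.col(predict_probs(model, featurise(records[te], prep)),
                                   ties.method = "first")]
    per_group[[g]] <- score(labels[te], pred)
  }

  # pooled stratified 5-fold CV baseline on the same records/seed
  folds <- stratified_folds(labels, 5L, child_seed(seed, "pooled"))
  pooled_pred <- character(length(records))
  for (k in 1:5) {
    tr <- which(folds != k); te <- which(folds == k)
    search <- random_search(records[tr], labels[tr], backend, variant, grid,
                            inner_k, child_seed(seed, paste0("pooled", k)),
                            min_df, ngram_range)
    prep <- build_preprocessing(records[tr], backend, variant, min_df, ngram_range)
    model <- fit_booster(featurise(records[tr], prep),
                         factor(labels[tr], levels = SERIES_CLASSES),
                         search$best, child_seed(seed, paste0("pooledfit", k)))
    pooled_pred[te] <- SERIES_CLASSES[max.col(
      predict_probs(model, featurise(records[te], prep)), ties.method = "first")]
  }
  pooled <- score(labels, pooled_pred)

  pooled_f1 <- stats::setNames(pooled$per_class$f1, pooled$per_class$class)
  delta <- lapply(per_group, function(ev)
    stats::setNames(ev$per_class$f1, ev$per_class$class) - pooled_f1)
  macro_delta <- vapply(per_group, function(ev) ev$macro_f1 - pooled$macro_f1, 0)
  list(per_group = per_group, pooled = pooled, delta_vs_pooled_cv = delta,
       macro_delta = macro_delta)
}

#' Learning curve over training-set fractions
#'
#' For each fraction a stratified random subset of the training records is
#' drawn (seeded), a model is trained on it (with a random hyperparameter
#' search scored by stratified CV on the subset) and evaluated on the fixed
#' held-out test records; [detect_saturation()] is then applied to the macro
#' F1 curve. Fractions too small to contain every class are skipped with a
#' warning.
#'
#' @inheritParams nested_cv_train
#' @param test_records held-out labelled records, disjoint from \code{records}.
#' @param fractions increasing fractions in (0, 1]; the default grid is
#'   1, 2, 5, 10, 25, 50, 70 and 100 percent.
#' @param inner_k folds of the per-fraction hyperparameter search.
#' @return object of class \code{mrseries_curve}: list with \code{scores}
#'   (data.frame: fraction, n_train, macro_f1, weighted_f1, one f1_<class>
#'   column per class), \code{breakpoint} (estimated fraction or NA),
#'   \code{stationary_after_breakpoint} (logical) and \code{fit} (the
#'   [detect_saturation()] result).
#' @export
learning_curve <- function(records, test_records,
                           fractions = c(0.01, 0.02, 0.05, 0.10, 0.25, 0.50, 0.70, 1.00),
                           backend = c("engineered", "native-categorical"),
                           variant = "all", grid = default_grid(), seed = 1L,
                           inner_k = 5L, min_df = 0.01, ngram_range = c(1L, 5L)) {
  backend <- match.arg(backend)
  stopifnot(all(diff(fractions) > 0), all(fractions > 0), all(fractions <= 1))
  labels <- vapply(records, function(r) r$label %||% NA_character_, character(1))
  test_labels <- vapply(test_records, function(r) r$label %||% NA_character_, character(1))
  check_labels(labels)
  if (length(intersect(vapply(records, `[[`, character(1), "series_uid"),
                       vapply(test_records, `[[`, character(1), "series_uid"))) > 0L)
    stop("test_records overlap the training records")

  rows <- list()
  for (f in fractions) {
    n_target <- round(f * length(records))
    if (n_target < length(SERIES_CLASSES)) {
      warning(sprintf("fraction %.3g gives %d records (< %d classes); skipped",
                      f, n_target, length(SERIES_CLASSES)))
      next
    }
    idx <- stratified_fraction(labels, f, child_seed(seed, paste0("frac", f)))
    if (length(unique(labels[idx])) < length(SERIES_CLASSES)) {
      warning(sprintf("fraction %.3g misses a class; skipped", f))
      next
    }
    search <- random_search(records[idx], labels[idx], backend, variant, grid,
                            inner_k, child_seed(seed, paste0("lcsearch", f)),
                            min_df, ngram_range)
    prep <- build_preprocessing(records[idx], backend, variant, min_df, ngram_range)
    model <- fit_booster(featurise(records[idx], prep),
                         factor(labels[idx], levels = SERIES_CLASSES),
                         search$best, child_seed(seed, paste0("lcfit", f)))
    pred <- SERIES_CLASSES[max.col(
      predict_probs(model, featurise(test_records, prep)), ties.method = "first")]
    ev <- score(test_labels, pred)
    row <- data.frame(fraction = f, n_train = length(idx), macro_f1 = ev$macro_f1,
                      weighted_f1 = ev$weighted_f1)
    for (cl in SERIES_CLASSES)
      row[[paste0("f1_", cl)]] <- ev$per_class$f1[ev$per_class$class == cl]
    rows[[length(rows) + 1L]] <- row
  }
  scores <- do.call(rbind, rows)
  sat <- if (nrow(scores) >= 4L)
    detect_saturation(scores$fraction, scores$macro_f1)
  else list(breakpoint = NA_real_, stationary = NA)
  structure(list(scores = scores, breakpoint = sat$breakpoint,
                 stationary_after_breakpoint = sat$stationary, fit = sat),
            class = "mrseries_curve")
}

# stratified subset of approximately fraction f, >= 1 record per present class
stratified_fraction <- function(labels, f, seed) {
  with_seed(seed, {
    idx <- integer(0)
    for (cl in sort_c(unique(labels))) {
      pool <- which(labels == cl)
      n_cl <- max(1L, round(f * length(pool)))
      idx <- c(idx, pool[sample.int(length(pool), n_cl)])
    }
    sort(idx)
  })
}

#' Two-step learning-curve saturation detector
#'
#' Step 1 asks whether the rate of improvement changes: a two-piece
#' (segmented) linear regression of score on log-fraction, with the
#' breakpoint profiled over the interior grid points, is compared with a
#' single straight line by an F-test (2 extra parameters) at
#' \code{alpha}. Step 2 confirms stationarity after the change point: a
#' t-test of the post-breakpoint slope against zero; the curve is stationary
#' when that slope is not significantly different from 0. Without a detected
#' rate change the breakpoint is \code{NA} and stationarity refers to the
#' single fitted slope.
#'
#' @param fractions numeric vector (>= 4 points, strictly increasing, in
#'   (0, 1]).
#' @param scores performance at each fraction.
#' @param alpha significance threshold (default 0.05).
#' @return list with \code{breakpoint} (fraction, or NA), \code{stationary}
#'   (logical), \code{post_slope}, \code{p_breakpoint}, \code{p_slope}.
#' @export
detect_saturation <- function(fractions, scores, alpha = 0.05) {
  n <- length(fractions)
  if (n < 4L) stop("need >= 4 points")
  stopifnot(length(scores) == n, all(diff(fractions) > 0))
  x <- log(fractions)
  y <- scores
  eps <- 1e-12

  fit0 <- stats::lm(y ~ x)
  sse0 <- sum(stats::residuals(fit0)^2)

  # profile the breakpoint over interior grid points (>= 2 points per piece)
  cands <- x[2:(n - 2L)]
  seg_fits <- lapply(cands, function(cx) stats::lm(y ~ x + pmax(x - cx, 0)))
  sses <- vapply(seg_fits, function(m) sum(stats::residuals(m)^2), 0)
  best <- which.min(sses)
  fit1 <- seg_fits[[best]]
  sse1 <- sses[best]

  # a single line fits exactly: no rate change; stationary iff that line is flat
  if (sse0 < eps) {
    slope <- unname(stats::coef(fit0)[2])
    flat <- abs(slope) < 1e-8
    return(list(breakpoint = NA_real_, stationary = flat,
                post_slope = slope, p_breakpoint = 1,
                p_slope = if (flat) 1 else 0))
  }

  df1 <- n - 3L
  f_stat <- ((sse0 - sse1) / 2) / max(sse1 / df1, eps)
  p_break <- stats::pf(f_stat, 2, df1, lower.tail = FALSE)

  if (p_break < alpha) {
    co <- stats::coef(fit1)
    v <- stats::vcov(fit1)
    post_slope <- co[2] + co[3]
    se <- sqrt(v[2, 2] + v[3, 3] + 2 * v[2, 3])
    if (!is.finite(se) || se < eps) {
      stationary <- abs(post_slope) < 1e-8
      p_slope <- if (stationary) 1 else 0
    } else {
      t_stat <- post_slope / se
      p_slope <- 2 * stats::pt(abs(t_stat), df1, lower.tail = FALSE)
      stationary <- p_slope >= alpha
    }
    list(breakpoint = exp(cands[best]), stationary = unname(stationary),
         post_slope = unname(post_slope), p_breakpoint = p_break,
         p_slope = unname(p_slope))
  } else {
    co <- summary(fit0)$coefficients
    slope <- co["x", "Estimate"]
    se <- co["x", "Std. Error"]
    if (!is.finite(se) || se < eps) {
      stationary <- abs(slope) < 1e-8
      p_slope <- if (stationary) 1 else 0
    } else {
      p_slope <- co["x", "Pr(>|t|)"]
      stationary <- p_slope >= alpha
    }
    list(breakpoint = NA_real_, stationary = unname(stationary),
         post_slope = unname(slope), p_breakpoint = p_break,
         p_slope = unname(p_slope))
  }
}

#' Flatten evaluation reports into a results table
#'
#' One row per (variant, backend, split); per-class F1 columns with per-fold
#' standard deviations when fold-level results are available.
#'
#' @param reports named list of \code{mrseries_eval} objects; names are used
#'   as the split/run label.
#' @return data.frame.
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    ev <- reports[[nm]]
    row <- data.frame(run = nm, macro_f1 = ev$macro_f1,
                      weighted_f1 = ev$weighted_f1, n = ev$n)
    for (cl in SERIES_CLASSES) {
      row[[paste0("f1_", cl)]] <- ev$per_class$f1[ev$per_class$class == cl]
      if (!is.null(ev$per_fold)) {
        sds <- vapply(ev$per_fold, function(fr)
          fr$per_class$f1[fr$per_class$class == cl], 0)
        row[[paste0("f1_", cl, "_sd")]] <- stats::sd(sds)
      }
    }
    row
  }))
}
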