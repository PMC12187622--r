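# independent contingency-based metric computation for cross-checking score()
brute_metrics <- function(true, pred) {
  out <- list()
  for (cl in series_classes()) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out[[cl]] <- c(precision = p, recall = r, f1 = f)
  }
  out
}

test_that("score reproduces the hand-computed four-sample example", {
  ev <- score(c("T2W", "T2W", "DWI", "DWI"), c("T2W", "DWI", "DWI", "DWI"))
  t2w <- ev$per_class[ev$per_class$class == "T2W", ]
  dwi <- ev$per_class[ev$per_class$class == "DWI", ]
  expect_equal(t2w$precision, 1.0)
  expect_equal(t2w$recall, 0.5)
  expect_equal(t2w$f1, 2 / 3)
  expect_equal(dwi$precision, 2 / 3)
  expect_equal(dwi$recall, 1.0)
  expect_equal(dwi$f1, 0.8)
  expect_identical(sum(ev$confusion), 4L)
})

test_that("perfect and degenerate predictors score as expected", {
  truth <- rep(series_classes(), each = 4)
  ev <- score(truth, truth)
  expect_identical(ev$macro_f1, 1)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0L,
                  ev$confusion[lower.tri(ev$confusion)] == 0L))
  # everything predicted T2W: T2W recall 1, all other classes 0
  ev2 <- score(truth, rep("T2W", length(truth)))
  expect_equal(ev2$per_class$recall[ev2$per_class$class == "T2W"], 1)
  expect_true(all(ev2$per_class$f1[ev2$per_class$class != "T2W"] == 0))
  expect_error(score(truth, truth[-1]), "length")
  expect_error(score(c("T2W", "FLAIR"), c("T2W", "T2W")), "unknown label")
})

test_that("score matches a brute-force contingency computation", {
  set.seed(23)
  for (i in seq_len(300)) {
    n <- sample(3:40, 1)
    truth <- sample(series_classes(), n, replace = TRUE)
    pred <- sample(series_classes(), n, replace = TRUE)
    ev <- score(truth, pred)
    bf <- brute_metrics(truth, pred)
    for (cl in series_classes()) {
      row <- ev$per_class[ev$per_class$class == cl, ]
      expect_equal(c(precision = row$precision, recall = row$recall, f1 = row$f1),
                   bf[[cl]])
    }
    expect_equal(ev$macro_f1, mean(vapply(bf, `[[`, 0, "f1")))
    expect_identical(sum(ev$confusion), n)
  }
})

test_that("leave-one-centre-out folds partition records by centre", {
  recs <- generate_dataset(small_spec(24, k = 3, seed = 61))
  res <- logocv(recs, backend = "engineered", grid = quick_grid(1L),
                seed = 3, inner_k = 2L)
  expect_identical(sort(names(res$per_group)),
                   c("centre_01", "centre_02", "centre_03"))
  centres <- vapply(recs, `[[`, character(1), "centre_id")
  ns <- vapply(res$per_group, `[[`, 0L, "n")
  expect_identical(unname(ns[names(table(centres))]), unname(as.integer(table(centres))))
  expect_identical(sum(ns), length(recs))
  expect_length(res$delta_vs_pooled_cv, 3L)
  expect_error(logocv(recs[centres == "centre_01"], grid = quick_grid(1L)),
               ">= 2 centres")
})

test_that("learning curve uses the full set at fraction 1 and is deterministic", {
  recs <- generate_dataset(small_spec(40, seed = 62))
  test_recs <- generate_dataset(small_spec(15, seed = 63))
  fr <- c(0.1, 0.25, 0.5, 0.75, 1.0)
  c1 <- learning_curve(recs, test_recs, fractions = fr, backend = "engineered",
                       grid = quick_grid(1L), seed = 4, inner_k = 2L)
  expect_identical(c1$scores$fraction, fr)
  expect_identical(c1$scores$n_train[c1$scores$fraction == 1], length(recs))
  c2 <- learning_curve(recs, test_recs, fractions = fr, backend = "engineered",
                       grid = quick_grid(1L), seed = 4, inner_k = 2L)
  expect_identical(c1$scores, c2$scores)
  # separable synthetic data is learned to high accuracy by the full fraction
  expect_gte(c1$scores$macro_f1[c1$scores$fraction == 1], 0.9)
  # too-small fractions are skipped with a warning
  expect_warning(
    c3 <- learning_curve(recs, test_recs, fractions = c(0.001, 0.5, 0.7, 0.85, 1.0),
                         backend = "engineered", grid = quick_grid(1L),
                         seed = 4, inner_k = 2L),
    "skipped")
  expect_false(0.001 %in% c3$scores$fraction)
})

test_that("training and test sets must be disjoint for learning curves", {
  recs <- generate_dataset(small_spec(10, seed = 64))
  expect_error(learning_curve(recs, recs, grid = quick_grid(1L)), "overlap")
})

test_that("saturation detector handles planted, constant and linear curves", {
  fr <- c(0.01, 0.02, 0.05, 0.10, 0.25, 0.50, 0.70, 1.00)
  # analytic piecewise curve: rise to 0.9 at fraction 0.1, then flat
  y <- ifelse(fr <= 0.1, 0.5 + 0.4 * (fr / 0.1), 0.9)
  d <- detect_saturation(fr, y)
  gap <- abs(which.min(abs(fr - d$breakpoint)) - which(fr == 0.1))
  expect_lte(gap, 1L)
  expect_true(d$stationary)
  # constant curve: no breakpoint, stationary
  dc <- detect_saturation(fr, rep(0.87, 8))
  expect_true(is.na(dc$breakpoint))
  expect_true(dc$stationary)
  # strictly increasing line (in the fitted log-fraction scale): not stationary
  dl <- detect_saturation(fr, 0.5 + 0.05 * log(fr))
  expect_true(is.na(dl$breakpoint))
  expect_false(dl$stationary)
  expect_error(detect_saturation(fr[1:3], y[1:3]), ">= 4")
})

test_that("saturation detector recovers noisy planted breakpoints", {
  fr <- c(0.01, 0.02, 0.05, 0.10, 0.25, 0.50, 0.70, 1.00)
  set.seed(33)
  hits <- 0L
  n_sim <- 100L
  for (i in seq_len(n_sim)) {
    bp <- 0.10
    y <- ifelse(fr <= bp, 0.5 + 0.4 * (log(fr / 0.01) / log(bp / 0.01)), 0.9) +
      stats::rnorm(8, 0, 0.01)
    d <- detect_saturation(fr, y)
    if (!is.na(d$breakpoint) &&
        abs(which.min(abs(fr - d$breakpoint)) - which(fr == bp)) <= 1L)
      hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("report tables carry per-class F1 and fold SDs", {
  recs <- generate_dataset(small_spec(30, seed = 65))
  fit <- nested_cv_train(recs, backend = "engineered", grid = quick_grid(1L),
                         seed = 2, inner_k = 2L)
  tab <- report_table(list(cv = fit$report))
  expect_identical(tab$run, "cv")
  expect_true(all(paste0("f1_", series_classes()) %in% names(tab)))
  expect_true(all(paste0("f1_", series_classes(), "_sd") %in% names(tab)))
})
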