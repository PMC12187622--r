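make_record <- function(fields, uid = "s1") {
  structure(list(series_uid = uid, study_uid = "st", centre_id = "c",
                 fields = fields, raw = list(), n_instances = 1L),
            class = "mrseries_record")
}

records_from_values <- function(field, values) {
  lapply(seq_along(values), function(i)
    make_record(stats::setNames(list(values[i]), field), uid = paste0("s", i)))
}

test_that("column typing separates numeric-strings from categoricals", {
  recs <- lapply(1:3, function(i) make_record(list(
    a = c("90 92", "100", "-")[i],
    b = c("t2 ax", "600", "x")[i],
    c = "-",
    d = c("1.5", "-", "2.25e1")[i]), uid = paste0("s", i)))
  typing <- infer_column_typing(recs)
  expect_identical(typing[["a"]], "numeric-string")
  expect_identical(typing[["b"]], "categorical")
  expect_identical(typing[["c"]], "categorical")
  expect_identical(typing[["d"]], "numeric-string")
})

# independent brute-force n-gram document-frequency counter (no memoisation,
# different code path from the package)
brute_vocab <- function(values, min_df, nmin = 1L, nmax = 5L) {
  seen <- list()
  for (v in values) {
    if (v == "-") next
    w <- strsplit(v, " ", fixed = TRUE)[[1]]
    grams <- character(0)
    for (n in nmin:nmax) {
      if (n > length(w)) next
      for (i in 1:(length(w) - n + 1))
        grams <- c(grams, paste(w[i:(i + n - 1)], collapse = " "))
    }
    for (g in unique(grams)) seen[[g]] <- (seen[[g]] %||% 0L) + 1L
  }
  df <- unlist(seen) / length(values)
  df <- df[df >= min_df]
  df[order(names(df), method = "radix")]
}

test_that("vocabulary equals a brute-force document-frequency counter", {
  recs <- generate_dataset(small_spec(25, seed = 41))
  values <- vapply(recs, function(r) r$fields$SeriesDescription, character(1))
  vocab <- build_vocabulary(recs, "SeriesDescription", min_df = 0.01)
  expected <- brute_vocab(values, 0.01)
  expect_identical(vocab$tokens, names(expected))
  expect_equal(as.numeric(vocab$document_frequency), as.numeric(expected))
})

test_that("vocabulary respects min_df and ngram_range boundaries", {
  vals <- c(rep("t2 ax", 150), rep("dwi b50", 49), "unique stray")
  recs <- records_from_values("SeriesDescription", vals)
  vocab <- build_vocabulary(recs, "SeriesDescription", min_df = 0.01)
  expect_true("t2" %in% vocab$tokens)
  expect_identical(unname(vocab$document_frequency["t2 ax"]), 0.75)
  expect_false("unique" %in% vocab$tokens)  # df = 1/200 < 0.01
  expect_false("stray" %in% vocab$tokens)
  # min_df -> 0 keeps everything, including the full n-gram set of "a b"
  v2 <- build_vocabulary(records_from_values("f", "a b"), "f", min_df = 1e-9)
  expect_identical(v2$tokens, c("a", "a b", "b"))
  # every retained token re-checks against its own df
  expect_true(all(vocab$document_frequency >= vocab$min_df))
})

test_that("numeric-string summaries match hand computation", {
  expect_equal(summarise_numeric_string("1.0 2.0 4.0"),
               c(n_chars = 11, sum = 7, mean = 7 / 3, min = 1, max = 4))
  expect_equal(summarise_numeric_string("5"),
               c(n_chars = 1, sum = 5, mean = 5, min = 5, max = 5))
  expect_true(all(is.na(summarise_numeric_string("-"))))
})

test_that("numeric-string summaries agree with an independent parser", {
  set.seed(19)
  for (i in seq_len(300)) {
    nums <- round(stats::runif(sample(1:6, 1), 0, 2000),
                  sample(0:3, 1))
    s <- paste(format(nums, trim = TRUE, scientific = FALSE), collapse = " ")
    got <- summarise_numeric_string(s)
    parsed <- as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    expect_identical(unname(got["n_chars"]), as.numeric(nchar(s)))
    expect_equal(unname(got["sum"]), sum(parsed))
    expect_equal(unname(got["mean"]), mean(parsed))
    expect_equal(unname(got["min"]), min(parsed))
    expect_equal(unname(got["max"]), max(parsed))
  }
})

test_that("vectorize produces counts, honours variants, never adds columns", {
  recs <- generate_dataset(small_spec(30, seed = 43))
  typing <- infer_column_typing(recs)
  cat_fields <- names(typing)[typing == "categorical"]
  vocabs <- lapply(cat_fields, function(f) build_vocabulary(recs, f, min_df = 0.01))
  names(vocabs) <- cat_fields

  fm <- vectorize(recs, typing, vocabs, "all")
  expect_identical(nrow(fm$x), length(recs))
  # token columns carry occurrence counts: check against a direct count
  r1 <- recs[[1]]$fields$SeriesDescription
  w1 <- strsplit(r1, " ")[[1]][1]
  col <- paste0("tok:SeriesDescription:", w1)
  if (col %in% colnames(fm$x)) {
    direct <- sum(strsplit(r1, " ")[[1]] == w1)
    expect_identical(unname(fm$x[1, col]), as.numeric(direct))
  }
  # a repeated token counts twice
  rec2 <- records_from_values("SeriesDescription", c("b b", "b c"))
  ty2 <- c(SeriesDescription = "categorical")
  vo2 <- list(SeriesDescription = build_vocabulary(rec2, "SeriesDescription", 0.01))
  x2 <- vectorize(rec2, ty2, vo2, "all")$x
  expect_identical(unname(x2[1, "tok:SeriesDescription:b"]), 2)

  # variants drop the right provenance
  fm_nosd <- vectorize(recs, typing, vocabs, "no_sd")
  expect_false(any(fm_nosd$provenance$field == "SeriesDescription"))
  fm_nofov <- vectorize(recs, typing, vocabs, "no_fov_sar")
  expect_false(any(fm_nofov$provenance$field %in% c("PercentPhaseFieldOfView", "SAR")))
  fm_both <- vectorize(recs, typing, vocabs, "no_sd_fov_sar")
  expect_false(any(fm_both$provenance$field %in%
                   c("SeriesDescription", "PercentPhaseFieldOfView", "SAR")))

  # unseen tokens at inference add no columns and are ignored
  recs_new <- generate_dataset(small_spec(10, seed = 44))
  fm_new <- vectorize(recs_new, typing, vocabs, "all")
  expect_identical(colnames(fm_new$x), colnames(fm$x))

  # determinism: identical record -> identical row
  fm_again <- vectorize(recs, typing, vocabs, "all")
  expect_identical(fm$x, fm_again$x)
})

test_that("categorical pass-through keeps raw values and maps '-' to NA", {
  rec <- records_from_values("SeriesDescription", c("t2 ax", "-", "t2 ax"))
  typing <- c(SeriesDescription = "categorical")
  ft <- passthrough_categorical(rec, typing, "all")
  expect_s3_class(ft$x[["cat:SeriesDescription"]], "factor")
  expect_identical(as.character(ft$x[["cat:SeriesDescription"]]),
                   c("t2 ax", NA, "t2 ax"))
  # unseen levels at prediction become NA
  rec2 <- records_from_values("SeriesDescription", "never seen")
  ft2 <- passthrough_categorical(rec2, typing, "all", levels = ft$levels)
  expect_true(is.na(ft2$x[["cat:SeriesDescription"]][1]))
})
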