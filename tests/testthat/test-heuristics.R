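test_that("plane detection follows the slice normal", {
  expect_identical(detect_plane(c(1, 0, 0, 0, 1, 0)), "axial")
  expect_identical(detect_plane(c(0, 1, 0, 0, 0, -1)), "sagittal")
  expect_identical(detect_plane(c(1, 0, 0, 0, 0, -1)), "coronal")
  # in-plane rotations keep the plane
  th <- 0.3
  expect_identical(detect_plane(c(cos(th), sin(th), 0, -sin(th), cos(th), 0)), "axial")
  # negating both triplets flips the normal but not the plane
  for (ori in list(c(1, 0, 0, 0, 1, 0), c(0, 1, 0, 0, 0, -1), c(1, 0, 0, 0, 0, -1)))
    expect_identical(detect_plane(-ori), detect_plane(ori))
  # 45-degree oblique ties break towards the higher (more axial) index
  s <- 1 / sqrt(2)
  expect_warning(p <- detect_plane(c(1, 0, 0, 0, s, -s)), "tie")
  expect_identical(p, "axial")
  expect_error(detect_plane(c(0, 0, 0, 0, 1, 0)), "unit-norm")
})

test_that("spacing filter is strict at 4 mm and fail-open on missing", {
  expect_true(passes_spacing_filter(3.0))
  expect_false(passes_spacing_filter(4.0))
  expect_false(passes_spacing_filter(4.0001))
  expect_true(passes_spacing_filter(3.9999))
  expect_warning(keep <- passes_spacing_filter(NA), "missing")
  expect_true(keep)
  expect_error(passes_spacing_filter(-1), "negative")
})

test_that("eADC and synthetic-DWI flags match tokens and substrings", {
  expect_true(is_eadc("DERIVED PRIMARY EADC"))
  expect_true(is_eadc("derived primary eadc"))
  expect_false(is_eadc("DERIVED PRIMARY ADC"))
  expect_false(is_eadc("HEADCASE"))   # whole-token match only
  expect_false(is_eadc("-"))
  expect_true(is_synthetic_dwi("Synthetic b1400"))
  expect_true(is_synthetic_dwi("dwi SYNTHETIC high b"))
  expect_false(is_synthetic_dwi("ep2d diff b1000"))
  expect_false(is_synthetic_dwi(NA))
})

mk_rec <- function(raw = list(), fields = list(), uid = "s") {
  structure(list(series_uid = uid, study_uid = "st", centre_id = "c",
                 fields = fields, raw = raw, n_instances = 1L),
            class = "mrseries_record")
}

test_that("b-value reading handles standard and vendor private tags", {
  std <- mk_rec(raw = list(DiffusionBValue = "0 800 1400"))
  expect_identical(read_b_value(std), 1400)
  ge <- mk_rec(raw = list(PrivateBValueGE = "1000001400 8 0 0",
                          Manufacturer = "GE MEDICAL SYSTEMS"))
  expect_identical(read_b_value(ge), 1400)
  # GE without the 1e9 offset convention stays as stored
  expect_identical(read_b_value(ge, ge_offset_1e9 = FALSE), 1000001400)
  # plain GE values below 1e9 are taken as-is
  ge2 <- mk_rec(raw = list(PrivateBValueGE = "800", Manufacturer = "GE"))
  expect_identical(read_b_value(ge2), 800)
  si <- mk_rec(raw = list(PrivateBValueSiemens = "50 1000", Manufacturer = "SIEMENS"))
  expect_identical(read_b_value(si), 1000)
  # the standard tag wins over private tags
  both <- mk_rec(raw = list(DiffusionBValue = "600", PrivateBValueGE = "1000000050",
                            Manufacturer = "GE"))
  expect_identical(read_b_value(both), 600)
  # a non-GE manufacturer never consults the GE tag
  phl <- mk_rec(raw = list(PrivateBValueGE = "1000000050", Manufacturer = "Philips"))
  expect_true(is.na(read_b_value(phl)))
  expect_true(is.na(read_b_value(mk_rec())))
})

test_that("highest b-value selection ranks missing lowest, ties by series number", {
  mk_dwi <- function(b, sn, uid) mk_rec(raw = list(
    DiffusionBValue = if (is.na(b)) NA_character_ else as.character(b),
    SeriesNumber = as.character(sn)), uid = uid)
  s <- list(mk_dwi(50, 1, "a"), mk_dwi(1400, 2, "b"), mk_dwi(800, 3, "c"))
  expect_identical(select_highest_bvalue(s)$series_uid, "b")
  s2 <- list(mk_dwi(NA, 4, "a"), mk_dwi(800, 2, "b"))
  expect_identical(select_highest_bvalue(s2)$series_uid, "b")
  s3 <- list(mk_dwi(NA, 1, "a"), mk_dwi(NA, 5, "b"))
  expect_identical(select_highest_bvalue(s3)$series_uid, "b")
  expect_identical(select_highest_bvalue(s3[1])$series_uid, "a")
  expect_error(select_highest_bvalue(list()), "empty")
})

test_that("curation composes the rules into the planted triplet", {
  recs <- generate_dataset(distractor_spec(40, seed = 71))
  for (study in split_by_study(recs)) {
    cur <- curate_study(oracle_predictions(study), study)
    uid_of <- function(i) study[[i]]$series_uid
    truths <- lapply(study, `[[`, "truth")
    labels <- vapply(truths, `[[`, character(1), "label")

    # planted winners
    t2_target <- which(labels == "T2W" & vapply(truths, function(t)
      t$plane == "ax" && !t$thick_t2w, logical(1)))
    adc_target <- which(labels == "ADC" & !vapply(truths, `[[`, logical(1), "is_eadc"))
    dwi_ok <- which(labels == "DWI" & !vapply(truths, `[[`, logical(1), "is_sdwi"))
    bvals <- vapply(truths[dwi_ok], function(t) t$b_value %||% -Inf, 0)
    dwi_target <- dwi_ok[which.max(bvals)]

    expect_identical(cur$triplet$T2W, uid_of(t2_target[1]))
    expect_identical(cur$triplet$ADC, uid_of(adc_target[1]))
    expect_identical(cur$triplet$DWI, uid_of(dwi_target))

    # excluded series never appear in the triplet
    excluded <- vapply(seq_along(study), function(i) {
      t <- truths[[i]]
      (labels[i] == "T2W" && (t$plane != "ax" || t$thick_t2w)) ||
        (labels[i] == "ADC" && t$is_eadc) ||
        (labels[i] == "DWI" && t$is_sdwi)
    }, logical(1))
    expect_false(any(unlist(cur$triplet) %in%
                     vapply(which(excluded), uid_of, character(1))))
    # every dropped series names at least one rule
    dropped <- cur$decisions[!cur$decisions$keep, ]
    expect_true(all(nzchar(dropped$rules_fired)))
  }
})

test_that("curation boundary and degenerate cases", {
  recs <- generate_dataset(synthetic_study_spec(
    1, centres = default_centres(1),
    label_mix = c(T2W = 1, DWI = 1, ADC = 1, DCE = 1, OTHERS = 1), seed = 72))
  study <- split_by_study(recs)[[1]]

  # one compliant series per slot: identity selection
  cur <- curate_study(oracle_predictions(study), study)
  labels <- vapply(study, `[[`, character(1), "label")
  expect_identical(cur$triplet$T2W, study[[which(labels == "T2W")]]$series_uid)
  expect_identical(cur$triplet$DWI, study[[which(labels == "DWI")]]$series_uid)
  expect_identical(cur$triplet$ADC, study[[which(labels == "ADC")]]$series_uid)

  # removing the DCE series does not change the triplet
  keep <- labels != "DCE"
  cur2 <- curate_study(oracle_predictions(study[keep]), study[keep])
  expect_identical(cur2$triplet, cur$triplet)

  # spacing exactly 4.0 mm excludes the only T2W -> empty slot
  t2i <- which(labels == "T2W")
  study[[t2i]]$raw$SpacingBetweenSlices <- "4.0"
  cur3 <- curate_study(oracle_predictions(study), study)
  expect_true(is.na(cur3$triplet$T2W))
  dec <- cur3$decisions[cur3$decisions$series_uid == study[[t2i]]$series_uid, ]
  expect_match(dec$rules_fired, "slice_spacing_ge_4mm")

  # predictions must cover every record
  expect_error(curate_study(oracle_predictions(study)[-1, ], study), "cover")
})
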