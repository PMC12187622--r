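# Five deterministic tag-based curation rules applied after classification to
# pick the ML-ready axial T2W / highest-b DWI / plain ADC triplet.

#' Detect the acquisition plane from orientation cosines
#'
#' The six ImageOrientationPatient values give the row and column direction
#' cosines; their cross product is the slice normal. The index (0, 1, 2) of
#' the normal's largest absolute component maps directly to sagittal, coronal
#' and axial. Near-ties are broken towards the higher index (axial-preferring)
#' with a warning.
#'
#' @param orientation_cosines numeric vector of 6 (row direction x3, column
#'   direction x3); each triplet must be unit-norm within 1e-3.
#' @return \code{"sagittal"}, \code{"coronal"} or \code{"axial"}.
#' @examples
#' detect_plane(c(1, 0, 0, 0, 1, 0))   # axial
#' detect_plane(c(0, 1, 0, 0, 0, -1))  # sagittal
#' @export
detect_plane <- function(orientation_cosines) {
  stopifnot(length(orientation_cosines) == 6L, !anyNA(orientation_cosines))
  r <- orientation_cosines[1:3]
  cc <- orientation_cosines[4:6]
  if (abs(sqrt(sum(r^2)) - 1) > 1e-3 || abs(sqrt(sum(cc^2)) - 1) > 1e-3)
    stop("orientation cosine triplets must be unit-norm (within 1e-3)")
  normal <- c(r[2] * cc[3] - r[3] * cc[2],
              r[3] * cc[1] - r[1] * cc[3],
              r[1] * cc[2] - r[2] * cc[1])
  a <- abs(normal)
  winners <- which(a >= max(a) - 1e-9)
  if (length(winners) > 1L)
    warning("ambiguous (oblique) orientation; tie broken towards axial")
  c("sagittal", "coronal", "axial")[max(winners)]
}

#' Slice-spacing filter for T2W
#'
#' Prostate T2W is acquired with roughly 3 mm between slices; thicker series
#' are excluded. Keeps spacings strictly below 4.0 mm. Missing spacing is
#' kept (fail-open, with a warning): the rule is an exclusion filter and a
#' silent drop of a valid series is worse than a false keep.
#'
#' @param slice_spacing_mm numeric or \code{NA}.
#' @return logical.
#' @export
passes_spacing_filter <- function(slice_spacing_mm) {
  if (is.na(slice_spacing_mm)) {
    warning("missing slice spacing: keeping series (fail-open)")
    return(TRUE)
  }
  if (slice_spacing_mm < 0) stop("negative slice spacing: ", slice_spacing_mm)
  slice_spacing_mm < 4.0
}

#' Is a series an exponential ADC?
#'
#' True iff the whitespace-split token set of the ImageType value contains
#' \code{"EADC"} as a whole token (case-insensitive); matching whole tokens
#' avoids hits inside unrelated words.
#'
#' @param image_type sanitised ImageType string.
#' @return logical.
#' @export
is_eadc <- function(image_type) {
  if (is.na(image_type) || image_type == "-") return(FALSE)
  toks <- toupper(strsplit(image_type, "[[:space:]]+")[[1]])
  "EADC" %in% toks
}

#' Is a series a synthetic (calculated) DWI?
#'
#' True iff the lower-cased series description contains the substring
#' \code{"synthetic"}.
#'
#' @param series_description description string.
#' @return logical.
#' @export
is_synthetic_dwi <- function(series_description) {
  if (is.na(series_description)) return(FALSE)
  grepl("synthetic", tolower(series_description), fixed = TRUE)
}

#' Read the diffusion b-value of a series
#'
#' Tries the standard tag (0018,9087) first; when absent, falls back to the
#' vendor dialect: the GE private tag (0043,1039) (first numeric element,
#' minus 1e9 when the stored value is >= 1e9, which covers b = 0) or the
#' Siemens private tag
#' (0019,100c). Multi-valued entries yield the maximum. All failures return
#' \code{NA}.
#'
#' @param record an \code{mrseries_record}.
#' @param manufacturer optional manufacturer string; defaults to the record's
#'   Manufacturer field.
#' @param ge_offset_1e9 apply the documented GE 1e9 offset convention
#'   (default TRUE).
#' @return numeric b-value in s/mm2, or \code{NA}.
#' @export
read_b_value <- function(record, manufacturer = NULL, ge_offset_1e9 = TRUE) {
  get_field <- function(f) {
    v <- record$raw[[f]] %||% record$fields[[f]]
    if (is.null(v) || is.na(v) || v == "-") NA_character_ else v
  }
  parse_nums <- function(v) {
    if (is.na(v)) return(numeric(0))
    nums <- suppressWarnings(as.numeric(strsplit(v, "[[:space:]]+")[[1]]))
    nums[!is.na(nums)]
  }
  std <- parse_nums(get_field("DiffusionBValue"))
  if (length(std) > 0L) return(max(std))

  manufacturer <- manufacturer %||% get_field("Manufacturer") %||% ""
  man <- tolower(if (is.na(manufacturer)) "" else manufacturer)
  if (grepl("ge", man, fixed = TRUE)) {
    ge <- parse_nums(get_field("PrivateBValueGE"))
    if (length(ge) > 0L) {
      b <- ge[1]
      if (ge_offset_1e9 && b >= 1e9) b <- b - 1e9
      return(b)
    }
  }
  if (grepl("siemens", man, fixed = TRUE)) {
    si <- parse_nums(get_field("PrivateBValueSiemens"))
    if (length(si) > 0L) return(max(si))
  }
  NA_real_
}

#' Select the highest b-value DWI
#'
#' PI-RADS v2.1 deems a single high-b (~1400 s/mm2) DWI sufficient, so among
#' several DWI series the one with the largest b-value is kept. Series with
#' missing b-values rank lowest; ties break towards the highest series
#' number.
#'
#' @param dwi_series non-empty list of \code{mrseries_record}.
#' @return the selected record.
#' @export
select_highest_bvalue <- function(dwi_series) {
  if (length(dwi_series) == 0L) stop("empty DWI list")
  if (length(dwi_series) == 1L) return(dwi_series[[1]])
  b <- vapply(dwi_series, function(r) {
    v <- suppressWarnings(read_b_value(r))
    if (is.na(v)) -Inf else v
  }, 0)
  sn <- vapply(dwi_series, series_number_of, 0)
  dwi_series[[order(-b, -sn)[1L]]]
}

series_number_of <- function(record) {
  v <- record$raw[["SeriesNumber"]] %||% record$fields[["SeriesNumber"]]
  n <- suppressWarnings(as.numeric(v))
  if (length(n) == 0L || is.na(n)) 0 else n
}

orientation_of <- function(record) {
  v <- record$raw[["ImageOrientationPatient"]]
  if (is.null(v) || is.na(v)) return(NULL)
  nums <- suppressWarnings(as.numeric(strsplit(v, "[[:space:]]+")[[1]]))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 6L) return(NULL)
  nums[1:6]
}

spacing_of <- function(record) {
  v <- record$raw[["SpacingBetweenSlices"]] %||% record$fields[["SpacingBetweenSlices"]]
  if (is.null(v) || is.na(v) || v == "-") return(NA_real_)
  n <- suppressWarnings(as.numeric(strsplit(v, "[[:space:]]+")[[1]]))
  n <- n[!is.na(n)]
  if (length(n) == 0L) NA_real_ else max(n)
}

#' Curate one study into an ML-ready triplet
#'
#' Applies the five rules to the predicted labels of a study's series:
#' \itemize{
#'   \item predicted T2W: keep only axial-plane series with slice spacing
#'     < 4 mm;
#'   \item predicted ADC: drop exponential ADC;
#'   \item predicted DWI: drop synthetic DWI, then keep the highest-b series;
#' }
#' and resolves residual multiplicity (e.g. two compliant axial T2W) towards
#' the highest series number, flagged in the decision detail. Slots with no
#' surviving candidate are reported empty.
#'
#' @param predictions data.frame with \code{series_uid} and
#'   \code{predicted_label} (e.g. from [predict_series()]), covering all
#'   \code{records}.
#' @param records list of \code{mrseries_record} for one study.
#' @return list with \code{triplet} (named list T2W/DWI/ADC of series UIDs or
#'   \code{NA}) and \code{decisions} (data.frame: series_uid, predicted_label,
#'   slot, keep, rules_fired, detail).
#' @export
curate_study <- function(predictions, records) {
  uids <- vapply(records, `[[`, character(1), "series_uid")
  if (!all(uids %in% predictions$series_uid))
    stop("predictions must cover every record")
  pred <- predictions$predicted_label[match(uids, predictions$series_uid)]

  decisions <- data.frame(series_uid = uids, predicted_label = pred,
                          slot = NA_character_, keep = FALSE,
                          rules_fired = "", detail = "", stringsAsFactors = FALSE)
  mark <- function(i, keep, rules, detail, slot = NA_character_) {
    decisions$keep[i] <<- keep
    decisions$rules_fired[i] <<- paste(rules, collapse = ";")
    decisions$detail[i] <<- detail
    decisions$slot[i] <<- slot
  }

  triplet <- list(T2W = NA_character_, DWI = NA_character_, ADC = NA_character_)

  # --- T2W: axial plane + spacing filter
  t2_idx <- which(pred == "T2W")
  t2_ok <- integer(0)
  for (i in t2_idx) {
    ori <- orientation_of(records[[i]])
    plane <- if (is.null(ori)) "axial"  # fail-open when orientation is absent
             else tryCatch(detect_plane(ori), error = function(e) "unknown")
    if (plane != "axial") {
      mark(i, FALSE, "non_axial_plane", paste("plane:", plane), "T2W")
      next
    }
    sp <- spacing_of(records[[i]])
    keep_sp <- withCallingHandlers(passes_spacing_filter(sp),
                                   warning = function(w) invokeRestart("muffleWarning"))
    if (!keep_sp) {
      mark(i, FALSE, "slice_spacing_ge_4mm", sprintf("spacing: %.2f mm", sp), "T2W")
      next
    }
    t2_ok <- c(t2_ok, i)
  }
  if (length(t2_ok) > 0L) {
    sel <- t2_ok[order(-vapply(records[t2_ok], series_number_of, 0))][1L]
    for (i in t2_ok) {
      if (i == sel) {
        detail <- if (length(t2_ok) > 1L) "selected (highest series number among compliant)"
                  else "selected"
        mark(i, TRUE, "axial_plane;slice_spacing_lt_4mm", detail, "T2W")
      } else mark(i, FALSE, "residual_multiplicity", "another compliant axial T2W outranks", "T2W")
    }
    triplet$T2W <- uids[sel]
  }

  # --- ADC: drop eADC
  adc_idx <- which(pred == "ADC")
  adc_ok <- integer(0)
  for (i in adc_idx) {
    it <- records[[i]]$raw[["ImageType"]] %||% records[[i]]$fields[["ImageType"]] %||% "-"
    if (is_eadc(it)) {
      mark(i, FALSE, "eadc_excluded", "EADC token in ImageType", "ADC")
    } else adc_ok <- c(adc_ok, i)
  }
  if (length(adc_ok) > 0L) {
    sel <- adc_ok[order(-vapply(records[adc_ok], series_number_of, 0))][1L]
    for (i in adc_ok) {
      if (i == sel) mark(i, TRUE, "plain_adc",
                         if (length(adc_ok) > 1L) "selected (highest series number)" else "selected",
                         "ADC")
      else mark(i, FALSE, "residual_multiplicity", "another plain ADC outranks", "ADC")
    }
    triplet$ADC <- uids[sel]
  }

  # --- DWI: drop synthetic, then highest b-value
  dwi_idx <- which(pred == "DWI")
  dwi_ok <- integer(0)
  for (i in dwi_idx) {
    desc <- records[[i]]$raw[["SeriesDescription"]] %||%
      records[[i]]$fields[["SeriesDescription"]] %||% NA_character_
    if (is_synthetic_dwi(desc)) {
      mark(i, FALSE, "synthetic_dwi_excluded", "'synthetic' in description", "DWI")
    } else dwi_ok <- c(dwi_ok, i)
  }
  if (length(dwi_ok) > 0L) {
    chosen <- select_highest_bvalue(records[dwi_ok])
    sel <- dwi_ok[match(chosen$series_uid, uids[dwi_ok])]
    b_sel <- suppressWarnings(read_b_value(records[[sel]]))
    for (i in dwi_ok) {
      if (i == sel) {
        detail <- if (is.na(b_sel)) "selected (all b-values missing; highest series number)"
                  else sprintf("selected (b = %g)", b_sel)
        mark(i, TRUE, "highest_b_value", detail, "DWI")
      } else mark(i, FALSE, "lower_b_value", "higher-b DWI available", "DWI")
    }
    triplet$DWI <- uids[sel]
  }

  other_idx <- which(!(pred %in% c("T2W", "DWI", "ADC")))
  for (i in other_idx)
    mark(i, FALSE, "not_triplet_class", paste("predicted:", pred[i]), NA_character_)

  list(triplet = triplet, decisions = decisions)
}
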