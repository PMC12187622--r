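# Synthetic multi-centre prostate mpMRI fixture generator.
#
# Emulates per-series DICOM metadata (and optionally real Part 10 files) with
# centre-specific description vocabularies, vendor b-value tag dialects,
# configurable missingness and known ground-truth labels, so that the whole
# extraction -> features -> model -> heuristics pipeline is testable without
# patient data.

SERIES_CLASSES <- c("T2W", "DWI", "ADC", "DCE", "OTHERS")

# description template bank; {plane} and b{b} are substituted at generation
# time. Composed from vocabulary seen across vendors in prostate protocols.
DEFAULT_TEMPLATES <- list(
  T2W = c("t2 tse {plane}", "{plane} t2 fse", "t2w {plane} prostate",
          "t2 propeller {plane}", "{plane} t2 frfse"),
  DWI = c("ep2d diff b{b}", "dwi {plane} b{b}", "ep2d diff tra b{b}",
          "diffusion b{b} {plane}"),
  sDWI = c("synthetic b{b} dwi", "dwi synthetic high b{b}",
           "calculated synthetic b{b}"),
  ADC = c("adc map", "ep2d diff adc", "dwi adc {plane}", "adc mm2 s"),
  eADC = c("eadc map", "exp adc {plane}", "eadc"),
  DCE = c("dce dynamic {plane}", "t1 twist dynamic", "dyn contrast {plane}",
          "perfusion dce prostate"),
  OTHERS = c("localizer", "scout three plane", "t1 tse {plane}", "survey",
             "cal body", "b1 map {plane}", "t1 vibe {plane}")
)

DEFAULT_PLANE_WORDS <- c(ax = "ax", sag = "sag", cor = "cor")

VENDOR_NAMES <- c(GE = "GE MEDICAL SYSTEMS", Siemens = "SIEMENS",
                  Philips = "Philips Medical Systems", generic = "ACME IMAGING")
VENDOR_MODELS <- c(GE = "SIGNA ARCHITECT", Siemens = "MAGNETOM Skyra",
                   Philips = "Ingenia", generic = "OPENSCAN 3T")

#' Describe one acquisition centre
#'
#' A centre profile bundles the properties that make metadata look different
#' across sites: its scanner vendor (which sets the diffusion b-value tag
#' dialect), its series-description vocabulary, and per-field missingness.
#'
#' @param centre_id short identifier, e.g. \code{"centre_A"}.
#' @param vendor one of \code{"GE"}, \code{"Siemens"}, \code{"Philips"},
#'   \code{"generic"}. GE stores the b-value in private tag (0043,1039) offset
#'   by 1e9; Siemens in private tag (0019,100c); Philips/generic use the
#'   standard tag (0018,9087).
#' @param description_vocab named list: one character vector of description
#'   templates per label in \code{T2W, DWI, ADC, DCE, OTHERS} (plus optional
#'   \code{sDWI}/\code{eADC} variants); templates may contain \code{{plane}}
#'   and \code{b{b}} placeholders. Default: a shared template bank, so
#'   centres are identically distributed until [inject_centre_shift()] is
#'   applied.
#' @param missingness named probabilities in \[0,1\]: chance that a field is
#'   absent from all instances of a series at this centre.
#' @param plane_words named character vector giving this centre's words for
#'   the ax/sag/cor plane tokens.
#' @return object of class \code{mrseries_centre}.
#' @export
centre_profile <- function(centre_id, vendor = "generic",
                           description_vocab = DEFAULT_TEMPLATES,
                           missingness = c(SAR = 0.25,
                                           PercentPhaseFieldOfView = 0.2,
                                           SpacingBetweenSlices = 0.05,
                                           ScanOptions = 0.3,
                                           ManufacturerModelName = 0.1),
                           plane_words = DEFAULT_PLANE_WORDS) {
  vendor <- match.arg(vendor, names(VENDOR_NAMES))
  stopifnot(all(missingness >= 0 & missingness <= 1))
  need <- SERIES_CLASSES
  have <- vapply(need, function(l) length(description_vocab[[l]] %||% character(0)) > 0, TRUE)
  if (!all(have))
    stop("description_vocab needs >=1 template for: ", paste(need[!have], collapse = ", "))
  structure(list(centre_id = centre_id, vendor = vendor,
                 description_vocab = description_vocab,
                 missingness = missingness, plane_words = plane_words),
            class = "mrseries_centre")
}

#' Default centre set
#'
#' `k` identically distributed centres (shared vocabulary) whose vendors cycle
#' through the given list; heterogeneity beyond the vendor tag dialect is
#' introduced with [inject_centre_shift()].
#'
#' @param k number of centres.
#' @param vendors vendor per centre, recycled.
#' @return list of \code{mrseries_centre}.
#' @export
default_centres <- function(k, vendors = "generic") {
  vendors <- rep_len(vendors, k)
  lapply(seq_len(k), function(i)
    centre_profile(sprintf("centre_%02d", i), vendor = vendors[i]))
}

#' Specify a synthetic dataset
#'
#' @param n_studies number of studies to generate; studies are assigned to
#'   centres uniformly.
#' @param centres list of [centre_profile()] objects.
#' @param label_mix named integer vector: exact number of series of each label
#'   per study. The default emulates a typical mpMRI exam: two T2W (one
#'   axial + one sagittal/coronal), two DWI b-values, one ADC, one DCE and two
#'   accessory series.
#' @param seed integer; generation is a pure function of (spec, seed).
#' @param date_range two dates (YYYY-MM-DD) bounding acquisition dates.
#' @param p_extra_adc_eadc probability that an ADC slot beyond the first is an
#'   exponential ADC (label stays ADC; ImageType contains EADC).
#' @param p_sdwi probability that the lowest-b DWI slot of a study with >= 2
#'   DWI is a synthetic (calculated) DWI, flagged by "synthetic" in its
#'   description.
#' @param p_thick_t2w probability that a distractor T2W (slots beyond the
#'   first) is axial with slice spacing >= 4 mm instead of sagittal/coronal.
#' @param p_date fraction of series descriptions carrying an embedded
#'   date/time string (exercises the date-removal sanitisation rule).
#' @param b_value_pool b-values (s/mm2) sampled without replacement for a
#'   study's DWI series.
#' @param n_slices_range min/max instances (slices) per series.
#' @return object of class \code{mrseries_spec}.
#' @export
synthetic_study_spec <- function(n_studies, centres = default_centres(3),
                                 label_mix = c(T2W = 2, DWI = 2, ADC = 1,
                                               DCE = 1, OTHERS = 2),
                                 seed = 1L,
                                 date_range = c("2019-01-01", "2022-03-31"),
                                 p_extra_adc_eadc = 0.5, p_sdwi = 0.3,
                                 p_thick_t2w = 0.25, p_date = 0.2,
                                 b_value_pool = c(0, 50, 100, 400, 800, 1000, 1400),
                                 n_slices_range = c(3L, 6L)) {
  stopifnot(n_studies >= 1, length(centres) >= 1)
  stopifnot(all(label_mix >= 0), any(label_mix > 0))
  stopifnot(all(names(label_mix) %in% SERIES_CLASSES))
  structure(list(n_studies = as.integer(n_studies), centres = centres,
                 label_mix = label_mix, seed = as.integer(seed),
                 date_range = as.Date(date_range),
                 p_extra_adc_eadc = p_extra_adc_eadc, p_sdwi = p_sdwi,
                 p_thick_t2w = p_thick_t2w, p_date = p_date,
                 b_value_pool = b_value_pool,
                 n_slices_range = as.integer(n_slices_range)),
            class = "mrseries_spec")
}

# in-plane rotation keeps the slice normal exact while varying the cosines
plane_cosines <- function(plane, theta) {
  base <- switch(plane,
    ax  = list(r = c(1, 0, 0), c = c(0, 1, 0)),
    sag = list(r = c(0, 1, 0), c = c(0, 0, -1)),
    cor = list(r = c(1, 0, 0), c = c(0, 0, -1)))
  r <- cos(theta) * base$r + sin(theta) * base$c
  cc <- -sin(theta) * base$r + cos(theta) * base$c
  round(c(r, cc), 6)
}

fill_template <- function(template, plane_word, b) {
  s <- gsub("{plane}", plane_word, template, fixed = TRUE)
  gsub("{b}", format(b), s, fixed = TRUE)
}

random_date_decoration <- function(spec) {
  d <- format(spec$date_range[1] + floor(stats::runif(1) *
         as.numeric(diff(spec$date_range))), "%d/%m/%Y")
  style <- sample(3L, 1L)
  switch(style, d, gsub("/", "-", d),
         sprintf("%02d:%02d:%02d", sample(0:23, 1), sample(0:59, 1), sample(0:59, 1)))
}

# draw one series' intended tag values; returns list(tags = per-field raw
# values, truth = hidden generator state)
draw_series <- function(label, sub, centre, spec, plane, b_value, series_number) {
  v <- centre$vendor
  pw <- centre$plane_words[[plane]]
  vocab_key <- if (!is.null(sub)) sub else label
  templates <- centre$description_vocab[[vocab_key]] %||% centre$description_vocab[[label]]
  desc <- fill_template(sample(templates, 1L), pw, b_value %||% 0)
  if (stats::runif(1) < spec$p_date)
    desc <- paste(desc, random_date_decoration(spec))

  is_eadc <- identical(sub, "eADC")
  is_sdwi <- identical(sub, "sDWI")
  image_type <- switch(label,
    T2W = "ORIGINAL\\PRIMARY",
    DWI = if (is_sdwi) "DERIVED\\PRIMARY\\DIFFUSION\\CALC_BVALUE" else
          "ORIGINAL\\PRIMARY\\DIFFUSION\\NONE",
    ADC = if (is_eadc) "DERIVED\\PRIMARY\\EADC" else "DERIVED\\PRIMARY\\ADC",
    DCE = "ORIGINAL\\PRIMARY\\DYNAMIC",
    OTHERS = "ORIGINAL\\PRIMARY\\LOCALIZER")

  thick <- FALSE
  spacing <- switch(label,
    T2W = round(stats::runif(1, 3.0, 3.6), 2),
    DWI = round(stats::runif(1, 3.0, 4.5), 2),
    ADC = round(stats::runif(1, 3.0, 4.5), 2),
    DCE = round(stats::runif(1, 2.0, 4.0), 2),
    OTHERS = round(stats::runif(1, 3.0, 8.0), 2))
  if (label == "T2W" && !is.null(attr(plane, "thick"))) {
    spacing <- round(stats::runif(1, 4.2, 5.5), 2); thick <- TRUE
  }

  te <- switch(label, T2W = stats::runif(1, 90, 130), DWI = stats::runif(1, 55, 90),
               ADC = stats::runif(1, 55, 90), DCE = stats::runif(1, 1.5, 4),
               OTHERS = stats::runif(1, 5, 30))
  tr <- switch(label, T2W = stats::runif(1, 3000, 6500), DWI = stats::runif(1, 2500, 6000),
               ADC = stats::runif(1, 2500, 6000), DCE = stats::runif(1, 3.5, 8),
               OTHERS = stats::runif(1, 200, 2000))
  scanning <- switch(label, T2W = "SE", DWI = "EP\\SE", ADC = "EP\\SE",
                     DCE = "GR", OTHERS = sample(c("SE", "GR", "IR"), 1L))

  tags <- list(
    SeriesDescription = desc,
    ImageType = image_type,
    Modality = "MR",
    Manufacturer = VENDOR_NAMES[[v]],
    ManufacturerModelName = VENDOR_MODELS[[v]],
    ScanningSequence = scanning,
    SequenceVariant = sample(c("SK\\SP", "NONE", "SS"), 1L),
    ScanOptions = sample(c("FS", "SAT1", "PFP"), 1L),
    MRAcquisitionType = if (label == "DCE") "3D" else "2D",
    SliceThickness = format(round(spacing * stats::runif(1, 0.8, 1.0), 2)),
    RepetitionTime = format(round(tr, 2)),
    EchoTime = format(round(te, 2)),
    SpacingBetweenSlices = format(spacing),
    MagneticFieldStrength = sample(c("1.5", "3"), 1L),
    PercentPhaseFieldOfView = format(round(stats::runif(1, 70, 100), 1)),
    FlipAngle = format(round(switch(label, DCE = stats::runif(1, 8, 15),
                                    stats::runif(1, 90, 160)))),
    SAR = format(round(stats::runif(1, 0.1, 3.5), 4)),
    ImageOrientationPatient = paste(plane_cosines(plane, stats::runif(1, -0.25, 0.25)),
                                    collapse = "\\"),
    Rows = sample(c("256", "320", "384", "512"), 1L),
    Columns = sample(c("256", "320", "384", "512"), 1L),
    PixelSpacing = paste(rep(format(round(stats::runif(1, 0.3, 2.0), 3)), 2),
                         collapse = "\\"),
    PixelBandwidth = format(round(stats::runif(1, 100, 600))),
    InPlanePhaseEncodingDirection = sample(c("ROW", "COL"), 1L),
    SeriesNumber = format(series_number)
  )
  if (label == "DCE") {
    tags$NumberOfTemporalPositions <- format(sample(18:40, 1L))
    tags$ContrastBolusAgent <- sample(c("GADOLINIUM", "DOTAREM", "GADOVIST"), 1L)
  }
  if (label %in% c("DWI", "ADC") && !is.null(b_value)) {
    if (label == "DWI" || stats::runif(1) < 0.15) { # b-value sometimes leaks into ADC
      if (v == "GE") tags$PrivateBValueGE <- format(1e9 + b_value, scientific = FALSE)
      else if (v == "Siemens") tags$PrivateBValueSiemens <- format(b_value)
      else tags$DiffusionBValue <- format(b_value)
    }
  }

  # apply centre missingness
  for (f in names(centre$missingness))
    if (!is.null(tags[[f]]) && stats::runif(1) < centre$missingness[[f]])
      tags[[f]] <- NULL

  list(tags = tags,
       truth = list(label = label, plane = plane, b_value = b_value,
                    is_eadc = is_eadc, is_sdwi = is_sdwi, thick_t2w = thick,
                    series_number = series_number))
}

# plan the series of one study: labels, sub-types, planes, b-values
plan_study <- function(spec, centre) {
  plan <- list()
  mix <- spec$label_mix[spec$label_mix > 0]
  for (label in names(mix)) {
    n <- mix[[label]]
    if (label == "T2W") {
      for (j in seq_len(n)) {
        if (j == 1L) plane <- "ax"
        else if (stats::runif(1) < spec$p_thick_t2w) {
          plane <- "ax"; attr(plane, "thick") <- TRUE
        } else plane <- sample(c("sag", "cor"), 1L)
        plan[[length(plan) + 1L]] <- list(label = label, sub = NULL,
                                          plane = plane, b = NULL)
      }
    } else if (label == "DWI") {
      bs <- sort(sample(spec$b_value_pool, n))
      sdwi_slot <- if (n >= 2L && stats::runif(1) < spec$p_sdwi) 1L else 0L
      for (j in seq_len(n)) {
        sub <- if (j == sdwi_slot) "sDWI" else NULL
        b <- if (!is.null(sub)) max(spec$b_value_pool) else bs[j]
        plan[[length(plan) + 1L]] <- list(label = label, sub = sub,
                                          plane = "ax", b = b)
      }
    } else if (label == "ADC") {
      for (j in seq_len(n)) {
        sub <- if (j > 1L && stats::runif(1) < spec$p_extra_adc_eadc) "eADC" else NULL
        plan[[length(plan) + 1L]] <- list(label = label, sub = sub, plane = "ax",
                                          b = sample(spec$b_value_pool, 1L))
      }
    } else {
      for (j in seq_len(n))
        plan[[length(plan) + 1L]] <- list(label = label, sub = NULL,
                                          plane = sample(c("ax", "sag", "cor"), 1L),
                                          b = NULL)
    }
  }
  plan
}

#' Generate a labelled synthetic dataset
#'
#' Draws \code{spec$n_studies} studies; each study gets exactly the series
#' counts in \code{spec$label_mix}, generated from its centre's vocabulary,
#' vendor dialect and missingness. When \code{out_dir} is given, each series
#' is written as DICOM Part 10 files (one per slice) under
#' \code{out_dir/<study>/<series>/}, a ground-truth CSV
#' (\code{ground_truth.csv}) is written next to them, and the same intended
#' metadata is returned. Generation is a pure function of (spec, seed):
#' identical inputs give identical output, including on-disk bytes.
#'
#' @param spec a [synthetic_study_spec()].
#' @param out_dir optional output directory; \code{NULL} (default) generates
#'   metadata records only, which is much faster.
#' @param config tag configuration used to aggregate the intended per-instance
#'   values into per-series records.
#' @return list of labelled \code{mrseries_record} (each carries \code{label},
#'   \code{centre_id} and a \code{truth} list with the hidden generator state:
#'   plane, b-value, eADC/sDWI flags).
#' @export
generate_dataset <- function(spec, out_dir = NULL, config = default_tag_config()) {
  stopifnot(inherits(spec, "mrseries_spec"))
  if (length(spec$centres) == 0L) stop("empty centre list")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  }
  centre_ids <- vapply(spec$centres, `[[`, character(1), "centre_id")
  records <- list()
  truth_rows <- list()
  with_seed(spec$seed, {
    for (s in seq_len(spec$n_studies)) {
      centre <- spec$centres[[((s - 1L) %% length(spec$centres)) + 1L]]
      study_uid <- sprintf("%s.%d.%d", UID_ROOT, spec$seed, s)
      acq_date <- format(spec$date_range[1] + floor(stats::runif(1) *
                    as.numeric(diff(spec$date_range))), "%Y%m%d")
      plan <- plan_study(spec, centre)
      for (k in seq_along(plan)) {
        p <- plan[[k]]
        drawn <- draw_series(p$label, p$sub, centre, spec, p$plane, p$b,
                             series_number = k)
        series_uid <- sprintf("%s.%d.%d.%d", UID_ROOT, spec$seed, s, k)
        n_slices <- sample(spec$n_slices_range[1]:spec$n_slices_range[2], 1L)
        # occasionally one field varies across slices (exercises aggregation)
        per_instance <- lapply(drawn$tags, function(v) rep(v, n_slices))
        if (stats::runif(1) < 0.15 && !is.null(per_instance$EchoTime)) {
          alt <- format(round(as.numeric(drawn$tags$EchoTime) + 1.5, 2))
          per_instance$EchoTime[n_slices] <- alt
        }
        if (!is.null(out_dir))
          write_series_files(out_dir, study_uid, series_uid, acq_date,
                             centre$centre_id, per_instance, drawn$tags, n_slices)
        raw_joined <- lapply(per_instance, function(v) gsub("\\", " ", v, fixed = TRUE))
        rec <- build_series_record(series_uid, study_uid, centre$centre_id,
                                   c(raw_joined, list(.n = seq_len(n_slices))),
                                   config)
        rec$label <- drawn$truth$label
        rec$truth <- drawn$truth
        rec$acquisition_date <- acq_date
        records[[length(records) + 1L]] <- rec
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          series_uid = series_uid, study_uid = study_uid,
          centre_id = centre$centre_id, label = drawn$truth$label,
          acquisition_date = acq_date, stringsAsFactors = FALSE)
      }
    }
  })
  if (!is.null(out_dir)) {
    gt <- do.call(rbind, truth_rows)
    utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  }
  records
}

write_series_files <- function(out_dir, study_uid, series_uid, acq_date,
                               centre_id, per_instance, tags, n_slices) {
  sdir <- file.path(out_dir, study_uid, series_uid)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  tagmap <- default_tag_config()$fields
  vr_for <- c(SeriesDescription = "LO", ImageType = "CS", Modality = "CS",
              Manufacturer = "LO", ManufacturerModelName = "LO",
              ScanningSequence = "CS", SequenceVariant = "CS", ScanOptions = "CS",
              MRAcquisitionType = "CS", SliceThickness = "DS",
              RepetitionTime = "DS", EchoTime = "DS", SpacingBetweenSlices = "DS",
              MagneticFieldStrength = "DS", PercentPhaseFieldOfView = "DS",
              FlipAngle = "DS", SAR = "DS", DiffusionBValue = "FD",
              ContrastBolusAgent = "LO", ImageOrientationPatient = "DS",
              NumberOfTemporalPositions = "IS", Rows = "US", Columns = "US",
              PixelSpacing = "DS", PixelBandwidth = "DS",
              InPlanePhaseEncodingDirection = "CS", SeriesNumber = "IS",
              PrivateBValueGE = "IS", PrivateBValueSiemens = "IS")
  for (i in seq_len(n_slices)) {
    sop_uid <- sprintf("%s.%d", series_uid, i)
    els <- list(
      dcm_element(0x0008L, 0x0016L, "UI", SOP_CLASS_MR),
      dcm_element(0x0008L, 0x0018L, "UI", sop_uid),
      dcm_element(0x0008L, 0x0020L, "DA", acq_date),
      dcm_element(0x0020L, 0x000dL, "UI", study_uid),
      dcm_element(0x0020L, 0x000eL, "UI", series_uid),
      dcm_element(0x0020L, 0x0013L, "IS", format(i)),
      dcm_element(0x0012L, 0x0030L, "LO", centre_id),
      dcm_element(0x7fe0L, 0x0010L, "OW", rep(0L, 32L)) # placeholder pixels
    )
    has_private <- FALSE
    for (f in names(per_instance)) {
      val <- per_instance[[f]][i]
      if (is.null(val) || is.na(val)) next
      tag <- tagmap$tag[tagmap$name == f]
      if (length(tag) != 1L) next
      ge <- strsplit(tag, ",")[[1]]
      group <- strtoi(ge[1], 16L); element <- strtoi(ge[2], 16L)
      vr <- vr_for[[f]] %||% "LO"
      v <- if (vr %in% c("US")) as.integer(val)
           else if (vr == "FD") as.numeric(strsplit(val, "\\", fixed = TRUE)[[1]])
           else strsplit(val, "\\", fixed = TRUE)[[1]]
      els[[length(els) + 1L]] <- dcm_element(group, element, vr, v)
      if (f == "PrivateBValueGE") {
        els[[length(els) + 1L]] <- dcm_element(0x0043L, 0x0010L, "LO", "GEMS_PARM_01")
      } else if (f == "PrivateBValueSiemens") {
        els[[length(els) + 1L]] <- dcm_element(0x0019L, 0x0010L, "LO", "SIEMENS MR HEADER")
      }
    }
    dcm_write(file.path(sdir, sprintf("slice_%03d.dcm", i)), els, sop_uid)
  }
}

# deterministically mangle a vocabulary token, keeping {b}/{plane} placeholders
mangle_token <- function(tok) {
  if (tok == "{plane}") return(tok)
  if (grepl("{b}", tok, fixed = TRUE))
    return(gsub("b{b}", "q{b}x", tok, fixed = TRUE))
  paste0("q", paste(rev(strsplit(tok, "")[[1]]), collapse = ""), "x")
}

#' Inject a distribution shift into one centre
#'
#' Rewrites the target centre's description vocabulary (a deterministic,
#' seeded fraction \code{shift_strength} of its distinct template tokens is
#' replaced by tokens no other centre uses) and raises the missingness of the
#' informative acquisition tags proportionally. \code{shift_strength = 0} is
#' the identity; at 1 the centre's description vocabulary shares no literal
#' token with the other centres and its b-value/contrast/temporal tags are
#' mostly absent. This creates the out-of-distribution centre used to probe
#' leave-one-centre-out generalisation.
#'
#' @param spec a [synthetic_study_spec()].
#' @param target_centre centre id present in \code{spec}.
#' @param shift_strength real in \[0,1\].
#' @return a new \code{mrseries_spec}.
#' @export
inject_centre_shift <- function(spec, target_centre, shift_strength) {
  stopifnot(inherits(spec, "mrseries_spec"),
            shift_strength >= 0, shift_strength <= 1)
  ids <- vapply(spec$centres, `[[`, character(1), "centre_id")
  i <- match(target_centre, ids)
  if (is.na(i)) stop("unknown centre: ", target_centre)
  if (shift_strength == 0) return(spec)
  centre <- spec$centres[[i]]
  vocab <- centre$description_vocab
  toks <- unique(unlist(strsplit(unlist(vocab), " ", fixed = TRUE)))
  toks <- setdiff(toks, "{plane}")
  n_replace <- ceiling(shift_strength * length(toks))
  chosen <- with_seed(child_seed(spec$seed, paste0("shift_", target_centre)),
                      sample(sort_c(toks), n_replace))
  mangled <- vapply(chosen, mangle_token, character(1))
  remap <- stats::setNames(mangled, chosen)
  vocab <- lapply(vocab, function(templates) {
    vapply(templates, function(tpl) {
      words <- strsplit(tpl, " ", fixed = TRUE)[[1]]
      hit <- words %in% names(remap)
      words[hit] <- remap[words[hit]]
      paste(words, collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  })
  centre$description_vocab <- vocab
  if (shift_strength == 1)
    centre$plane_words <- vapply(centre$plane_words, mangle_token, character(1))
  bump <- c("DiffusionBValue", "PrivateBValueGE", "PrivateBValueSiemens",
            "ContrastBolusAgent", "NumberOfTemporalPositions", "ScanOptions",
            "ScanningSequence", "ImageType")
  miss <- centre$missingness
  for (f in bump) miss[[f]] <- max(miss[f], 0, na.rm = TRUE) +
    shift_strength * 0.9 * (1 - max(miss[f], 0, na.rm = TRUE))
  centre$missingness <- miss
  spec$centres[[i]] <- centre
  spec
}
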