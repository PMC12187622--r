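# DICOM metadata extraction: configured tag set -> one sanitised record per series.

#' Default tag configuration
#'
#' The standard MR header fields used to discriminate the five series types.
#' Each entry maps a field name to its DICOM tag. Besides the standard
#' diffusion b-value tag (0018,9087), the GE (0043,1039) and Siemens
#' (0019,100c) private b-value tags are extracted so the curation heuristics
#' can recover b-values under either vendor dialect.
#'
#' @param feature_set_variant one of \code{"all"}, \code{"no_sd"},
#'   \code{"no_fov_sar"}, \code{"no_sd_fov_sar"}: which fields the feature
#'   builders later drop (series description and/or percent-phase field of
#'   view + specific absorption rate).
#' @return object of class \code{mrseries_tag_config}: list with
#'   \code{fields} (data.frame: name, tag) and \code{feature_set_variant}.
#' @export
default_tag_config <- function(feature_set_variant = "all") {
  fields <- data.frame(
    name = c("SeriesDescription", "ImageType", "Modality", "Manufacturer",
             "ManufacturerModelName", "ScanningSequence", "SequenceVariant",
             "ScanOptions", "MRAcquisitionType", "SliceThickness",
             "RepetitionTime", "EchoTime", "SpacingBetweenSlices",
             "MagneticFieldStrength", "PercentPhaseFieldOfView", "FlipAngle",
             "SAR", "DiffusionBValue", "ContrastBolusAgent",
             "ImageOrientationPatient", "NumberOfTemporalPositions", "Rows",
             "Columns", "PixelSpacing", "PixelBandwidth",
             "InPlanePhaseEncodingDirection", "SeriesNumber",
             "PrivateBValueGE", "PrivateBValueSiemens"),
    tag = c("0008,103e", "0008,0008", "0008,0060", "0008,0070",
            "0008,1090", "0018,0020", "0018,0021",
            "0018,0022", "0018,0023", "0018,0050",
            "0018,0080", "0018,0081", "0018,0088",
            "0018,0087", "0018,0094", "0018,1314",
            "0018,1316", "0018,9087", "0018,0010",
            "0020,0037", "0020,0105", "0028,0010",
            "0028,0011", "0028,0030", "0018,0095",
            "0018,1312", "0020,0011",
            "0043,1039", "0019,100c"),
    stringsAsFactors = FALSE
  )
  tag_config(fields, feature_set_variant)
}

#' Build a tag configuration
#'
#' @param fields data.frame with columns \code{name} (unique field names) and
#'   \code{tag} (\code{"gggg,eeee"} strings).
#' @param feature_set_variant see [default_tag_config()].
#' @return an \code{mrseries_tag_config} object.
#' @export
tag_config <- function(fields, feature_set_variant = "all") {
  stopifnot(is.data.frame(fields), all(c("name", "tag") %in% names(fields)))
  if (anyDuplicated(fields$name)) stop("field names must be unique")
  bad <- !grepl("^[0-9a-fA-F]{4},[0-9a-fA-F]{4}$", fields$tag)
  if (any(bad)) stop("invalid DICOM tag(s): ", paste(fields$tag[bad], collapse = ", "))
  feature_set_variant <- match.arg(feature_set_variant,
                                   c("all", "no_sd", "no_fov_sar", "no_sd_fov_sar"))
  structure(list(fields = fields, feature_set_variant = feature_set_variant),
            class = "mrseries_tag_config")
}

# fields whose raw (unsanitised, sign-preserving) per-series value is kept in
# the record for the geometry-aware curation heuristics
GEOMETRY_FIELDS <- c("ImageOrientationPatient", "SpacingBetweenSlices",
                     "ImageType", "SeriesDescription", "Manufacturer",
                     "DiffusionBValue", "PrivateBValueGE",
                     "PrivateBValueSiemens", "SeriesNumber")

# build one SeriesMetadata record from per-field lists of raw per-instance values
build_series_record <- function(series_uid, study_uid, centre_id,
                                per_field_raw, config) {
  fields <- vapply(config$fields$name, function(f) {
    aggregate_field(per_field_raw[[f]] %||% NA_character_)
  }, character(1))
  raw <- lapply(intersect(GEOMETRY_FIELDS, config$fields$name), function(f) {
    v <- per_field_raw[[f]]
    v <- unique(v[!is.na(v)])
    if (length(v) == 0L) NA_character_ else paste(sort_c(v), collapse = " ")
  })
  names(raw) <- intersect(GEOMETRY_FIELDS, config$fields$name)
  structure(list(series_uid = series_uid, study_uid = study_uid,
                 centre_id = centre_id, fields = as.list(fields), raw = raw,
                 n_instances = length(per_field_raw[[".n"]] %||% 1L)),
            class = "mrseries_record")
}

#' Extract metadata for one DICOM series
#'
#' Reads every DICOM file in \code{series_dir}, aggregates each configured
#' field's per-slice values into one sanitised per-series value (unique
#' values, space-joined, see [aggregate_field()]), and returns one record.
#' Fields absent from all instances get the missing marker \code{"-"}.
#'
#' @param series_dir directory containing the files of a single series.
#' @param config an \code{mrseries_tag_config}; default [default_tag_config()].
#' @return an \code{mrseries_record}: list with \code{series_uid},
#'   \code{study_uid}, \code{centre_id}, \code{fields} (sanitised values),
#'   \code{raw} (unsanitised values for geometry-relevant fields) and
#'   \code{n_instances}.
#' @export
extract_series_metadata <- function(series_dir, config = default_tag_config()) {
  paths <- list.files(series_dir, full.names = TRUE, recursive = FALSE)
  paths <- paths[!dir.exists(paths)]
  datasets <- list()
  for (p in sort_c(paths)) {
    ds <- tryCatch(dcm_read(p), error = function(e) {
      warning("skipping unreadable file ", p, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(ds)) datasets[[length(datasets) + 1L]] <- ds
  }
  if (length(datasets) == 0L) stop("no readable DICOM files in ", series_dir)
  uids <- vapply(datasets, dcm_tag_string, character(1), tag = "0020,000e")
  if (length(unique(uids)) > 1L)
    stop("mixed SeriesInstanceUIDs in ", series_dir, ": ",
         paste(unique(uids), collapse = ", "))
  record_from_datasets(datasets, config)
}

record_from_datasets <- function(datasets, config) {
  per_field <- lapply(seq_len(nrow(config$fields)), function(i) {
    vapply(datasets, dcm_tag_string, character(1), tag = config$fields$tag[i])
  })
  names(per_field) <- config$fields$name
  per_field$.n <- seq_along(datasets)
  build_series_record(
    series_uid = dcm_tag_string(datasets[[1]], "0020,000e") %||% NA_character_,
    study_uid = dcm_tag_string(datasets[[1]], "0020,000d"),
    centre_id = dcm_tag_string(datasets[[1]], "0012,0030"), # ClinicalTrialSiteID
    per_field_raw = per_field, config = config)
}

#' Extract metadata for every series in a study directory
#'
#' Files are grouped by their SeriesInstanceUID regardless of directory
#' layout, so one flat directory with interleaved series is handled the same
#' as one subdirectory per series.
#'
#' @param study_dir directory containing the study's DICOM files (searched
#'   recursively).
#' @param config an \code{mrseries_tag_config}.
#' @return list of \code{mrseries_record}, ordered by series UID; empty (with
#'   a warning) for an empty directory.
#' @export
extract_study <- function(study_dir, config = default_tag_config()) {
  paths <- list.files(study_dir, full.names = TRUE, recursive = TRUE)
  datasets <- list()
  for (p in sort_c(paths)) {
    ds <- tryCatch(dcm_read(p), error = function(e) {
      warning("skipping unreadable file ", p, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(ds)) datasets[[length(datasets) + 1L]] <- ds
  }
  if (length(datasets) == 0L) {
    warning("no readable DICOM files under ", study_dir)
    return(list())
  }
  uids <- vapply(datasets, dcm_tag_string, character(1), tag = "0020,000e")
  out <- lapply(sort_c(unique(uids)), function(u) {
    record_from_datasets(datasets[uids == u], config)
  })
  out
}

#' Convert records to a metadata table
#'
#' One row per series; sanitised field values as columns, plus identifier
#' columns and \code{raw.<field>} columns preserving the unsanitised values of
#' geometry-relevant fields (orientation cosines keep their signs there).
#'
#' @param records list of \code{mrseries_record} (a \code{label} element, when
#'   present, becomes a column).
#' @return data.frame.
#' @export
records_to_table <- function(records) {
  stopifnot(length(records) > 0L)
  field_names <- names(records[[1]]$fields)
  raw_names <- names(records[[1]]$raw)
  rows <- lapply(records, function(r) {
    c(list(series_uid = r$series_uid, study_uid = r$study_uid %||% NA_character_,
           centre_id = r$centre_id %||% NA_character_,
           n_instances = r$n_instances,
           label = r$label %||% NA_character_),
      r$fields,
      stats::setNames(lapply(raw_names, function(f) r$raw[[f]] %||% NA_character_),
                      paste0("raw.", raw_names)))
  })
  do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Convert a metadata table back to records
#'
#' Inverse of [records_to_table()].
#'
#' @param tab data.frame as produced by [records_to_table()] (or read back
#'   from CSV/Parquet).
#' @return list of \code{mrseries_record}.
#' @export
table_to_records <- function(tab) {
  id_cols <- c("series_uid", "study_uid", "centre_id", "n_instances", "label")
  raw_cols <- grep("^raw\\.", names(tab), value = TRUE)
  field_cols <- setdiff(names(tab), c(id_cols, raw_cols))
  lapply(seq_len(nrow(tab)), function(i) {
    fields <- as.list(tab[i, field_cols, drop = FALSE])
    fields <- lapply(fields, function(v) {
      v <- as.character(v)
      if (is.na(v) || v == "") "-" else v
    })
    raw <- as.list(tab[i, raw_cols, drop = FALSE])
    names(raw) <- sub("^raw\\.", "", raw_cols)
    raw <- lapply(raw, function(v) if (is.na(v)) NA_character_ else as.character(v))
    r <- structure(list(series_uid = as.character(tab$series_uid[i]),
                        study_uid = as.character(tab$study_uid[i]),
                        centre_id = as.character(tab$centre_id[i]),
                        fields = fields, raw = raw,
                        n_instances = as.integer(tab$n_instances[i])),
                   class = "mrseries_record")
    if ("label" %in% names(tab) && !is.na(tab$label[i])) r$label <- as.character(tab$label[i])
    r
  })
}

#' Write a metadata table to disk
#'
#' @param tab data.frame from [records_to_table()].
#' @param path output path; written as Parquet when the extension is
#'   \code{.parquet} (requires the \pkg{arrow} package), CSV otherwise.
#' @return \code{path}, invisibly.
#' @export
write_metadata_table <- function(tab, path) {
  if (tolower(tools::file_ext(path)) == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("writing Parquet requires the 'arrow' package")
    arrow::write_parquet(tab, path)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a metadata table from disk
#'
#' @param path CSV or Parquet file written by [write_metadata_table()].
#' @return data.frame.
#' @export
read_metadata_table <- function(path) {
  if (tolower(tools::file_ext(path)) == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("reading Parquet requires the 'arrow' package")
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
}
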