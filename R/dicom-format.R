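# Minimal DICOM Part 10 codec: explicit VR little endian only.
#
# Scope is deliberately narrow — enough to write syntactically valid single-frame
# MR Image Storage files for the fixture generator and to read their headers
# back. Sequences with undefined length, big-endian and implicit-VR transfer
# syntaxes are out of scope and rejected explicitly.

TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1" # explicit VR little endian
SOP_CLASS_MR <- "1.2.840.10008.5.1.4.1.1.4"  # MR Image Storage
UID_ROOT <- "1.2.826.0.1.3680043.10.1511"    # synthetic fixture UID root

# VRs encoded with 2-byte reserved field + 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN", "UC", "UR")
# string-valued VRs (backslash-separated multiplicity)
TEXT_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
              "SH", "ST", "TM", "UI", "UC", "UR", "UT")

uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_le <- function(x) {
  # writeBin has no unsigned 32-bit; values here stay far below 2^31
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

dcm_element <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

encode_value <- function(vr, value) {
  if (vr %in% TEXT_VRS) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      b <- c(b, pad)
    }
    b
  } else if (vr == "US") {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "FL") {
    writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW", "UN")) {
    b <- as.raw(value)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    b
  } else {
    stop("unsupported VR for encoding: ", vr)
  }
}

encode_element <- function(el) {
  body <- encode_value(el$vr, el$value)
  head <- c(uint16_le(el$group), uint16_le(el$element), charToRaw(el$vr))
  if (el$vr %in% LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), uint32_le(length(body)), body)
  } else {
    stopifnot(length(body) < 65536L)
    c(head, uint16_le(length(body)), body)
  }
}

# elements: list of dcm_element(), any order; written sorted by (group, element)
dcm_write <- function(path, elements, sop_instance_uid) {
  ord <- order(vapply(elements, `[[`, 0, "group"),
               vapply(elements, `[[`, 0, "element"))
  elements <- elements[ord]
  body <- do.call(c, lapply(elements, encode_element))

  meta <- list(
    dcm_element(0x0002L, 0x0001L, "OB", c(0L, 1L)),
    dcm_element(0x0002L, 0x0002L, "UI", SOP_CLASS_MR),
    dcm_element(0x0002L, 0x0003L, "UI", sop_instance_uid),
    dcm_element(0x0002L, 0x0010L, "UI", TRANSFER_SYNTAX_ELE),
    dcm_element(0x0002L, 0x0012L, "UI", paste0(UID_ROOT, ".0.1"))
  )
  meta_body <- do.call(c, lapply(meta, encode_element))
  group_len <- encode_element(dcm_element(0x0002L, 0x0000L, "UL", length(meta_body)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_body, body), con)
  invisible(path)
}

read_uint16 <- function(b, pos) {
  as.integer(b[pos]) + 256L * as.integer(b[pos + 1L])
}
read_uint32 <- function(b, pos) {
  sum(as.numeric(b[pos + 0:3]) * c(1, 256, 65536, 16777216))
}

decode_value <- function(vr, bytes) {
  if (vr %in% TEXT_VRS) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    s <- sub("[ ]+$", "", s)
    if (s == "") character(0) else strsplit(s, "\\", fixed = TRUE)[[1]]
  } else if (vr == "US") {
    readBin(bytes, "integer", n = length(bytes) / 2L, size = 2,
            endian = "little", signed = FALSE)
  } else if (vr == "UL") {
    readBin(bytes, "integer", n = length(bytes) / 4L, size = 4, endian = "little")
  } else if (vr == "FL") {
    readBin(bytes, "numeric", n = length(bytes) / 4L, size = 4, endian = "little")
  } else if (vr == "FD") {
    readBin(bytes, "numeric", n = length(bytes) / 8L, size = 8, endian = "little")
  } else {
    bytes
  }
}

#' Read a DICOM file header
#'
#' Parses a DICOM Part 10 file written in the explicit VR little endian
#' transfer syntax and returns its data elements. Pixel data is returned as a
#' raw vector, not decoded.
#'
#' @param path path to a DICOM file.
#' @return named list keyed by lower-case \code{"gggg,eeee"} tag; each entry
#'   has \code{vr} and \code{value} (character vector for string VRs, numeric
#'   for binary VRs, raw otherwise).
#' @export
dcm_read <- function(path) {
  b <- readBin(path, "raw", n = file.size(path))
  if (length(b) < 134L || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path)
  pos <- 133L
  n <- length(b)
  out <- list()
  ts_checked <- FALSE
  while (pos + 7L <= n) {
    group <- read_uint16(b, pos)
    element <- read_uint16(b, pos + 2L)
    vr <- rawToChar(b[pos + 4:5])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) encoding at byte ", pos, " in ", path)
    if (vr %in% LONG_VRS) {
      len <- read_uint32(b, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- read_uint16(b, pos + 6L)
      pos <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length elements are not supported")
    if (pos + len - 1L > n) stop("truncated DICOM element in ", path)
    val_bytes <- if (len > 0) b[pos:(pos + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, element)
    out[[key]] <- list(vr = vr, value = decode_value(vr, val_bytes))
    if (!ts_checked && key == "0002,0010") {
      ts <- out[[key]]$value
      if (!identical(ts, TRANSFER_SYNTAX_ELE))
        stop("unsupported transfer syntax: ", ts)
      ts_checked <- TRUE
    }
    pos <- pos + len
  }
  out
}

# fetch a tag ("gggg,eeee") as a character scalar with multi-values joined by
# a single space; NA when absent or empty
dcm_tag_string <- function(ds, tag) {
  el <- ds[[tolower(tag)]]
  if (is.null(el) || length(el$value) == 0L) return(NA_character_)
  v <- el$value
  if (is.raw(v)) return(NA_character_)
  paste(as.character(v), collapse = " ")
}
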