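#' Sanitise a raw DICOM metadata value
#'
#' Applies the four-step sanitisation protocol used throughout the package,
#' in this fixed order:
#' \enumerate{
#'   \item delete date-like substrings matching
#'     \code{[0-9]+[/-:][0-9]+[/-:][0-9]+} (e.g. \code{01/02/2020},
#'     \code{12:30:45});
#'   \item map missing or empty values to the literal \code{"-"};
#'   \item replace each of the characters \code{| - ; , ( ) _ :} with a
#'     single space (the missing marker \code{"-"} itself is exempt);
#'   \item collapse runs of spaces to one space and trim.
#' }
#' The function is total and idempotent; a value that becomes empty after
#' cleaning is mapped to \code{"-"}.
#'
#' @param raw character vector (may contain \code{NA}).
#' @return character vector of sanitised values, never empty, never \code{NA}.
#' @examples
#' sanitise_value("t2w 01/02/2020 axial")  # "t2w axial"
#' sanitise_value("SAG|T2_(fse)")          # "SAG T2 fse"
#' sanitise_value(NA)                      # "-"
#' @export
sanitise_value <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- as.character(raw)
  # (1) remove dates
  x <- gsub("[0-9]+[/:-][0-9]+[/:-][0-9]+", "", x)
  x <- trimws(x)
  # (2) missing -> "-"
  x[is.na(x) | x == ""] <- "-"
  # (3) punctuation -> space, except the bare missing marker
  keep <- x == "-"
  x[!keep] <- gsub("[|;,()_:-]", " ", x[!keep])
  # (4) squeeze and trim
  x <- trimws(gsub(" +", " ", x))
  x[x == ""] <- "-"
  x
}

#' Aggregate per-instance values into one per-series value
#'
#' A DICOM series holds one file per slice; a field can therefore carry many
#' values per series. Each value is sanitised, the unique sanitised values are
#' taken, and they are joined with single spaces in lexicographic (C-locale)
#' order so the result does not depend on file read order. Missing entries are
#' dropped unless all entries are missing, in which case the result is
#' \code{"-"}.
#'
#' @param per_instance_values character vector of raw per-instance values
#'   (\code{NA} allowed).
#' @return single sanitised string.
#' @examples
#' aggregate_field(c("90", "90", "92"))  # "90 92"
#' aggregate_field(c(NA, NA))            # "-"
#' @export
aggregate_field <- function(per_instance_values) {
  vals <- sanitise_value(per_instance_values)
  vals <- unique(vals)
  vals <- vals[vals != "-"]
  if (length(vals) == 0L) return("-")
  paste(sort_c(vals), collapse = " ")
}
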