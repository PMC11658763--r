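#' @importFrom utils read.delim write.table
NULL

# Canonical column order of the per-read length table.
LT_COLUMNS <- c("read_id", "library_id", "feature_id",
                "five_p", "three_p", "length", "adapter", "polya_pass")

POLYA_LEVELS <- c("pass", "fail", "unknown")

#' Construct a per-read length table
#'
#' The length table is the central data structure of the package: one row per
#' sequenced molecule, recording the transcript it aligned to, its aligned
#' span in transcript coordinates and per-read filter flags. Coordinates are
#' 0-based, half-open (`five_p` inclusive, `three_p` exclusive), so
#' `length == three_p - five_p` is the number of templated nucleotides the
#' read covers on the transcript. This aligned span deliberately excludes
#' soft-clipped bases, adapters and the poly(A) tail, which would otherwise
#' inflate read length.
#'
#' @param read_id character, unique read identifiers.
#' @param library_id character, sequencing library (replicate) of each read.
#' @param feature_id character, transcript or gene the read aligned to.
#' @param five_p integer, 0-based transcript coordinate of alignment start.
#' @param three_p integer, 0-based half-open coordinate of alignment end.
#' @param adapter logical, whether the read carries a ligated 5' adapter
#'   (certifying a true 5' end). Defaults to `FALSE`.
#' @param polya_pass one of `"pass"`, `"fail"`, `"unknown"`: poly(A) tail
#'   estimation QC status. Defaults to `"unknown"`.
#' @param provenance optional character note recording source file and
#'   filters applied; stored as an attribute and propagated by filters.
#'
#' @return A `data.frame` with class `"length_table"` and columns
#'   `read_id`, `library_id`, `feature_id`, `five_p`, `three_p`, `length`,
#'   `adapter`, `polya_pass`.
#' @export
length_table <- function(read_id = character(), library_id = character(),
                         feature_id = character(), five_p = integer(),
                         three_p = integer(), adapter = FALSE,
                         polya_pass = "unknown", provenance = NULL) {
  n <- length(read_id)
  tab <- data.frame(
    read_id    = as.character(read_id),
    library_id = as.character(library_id),
    feature_id = as.character(feature_id),
    five_p     = as.integer(five_p),
    three_p    = as.integer(three_p),
    length     = as.integer(three_p) - as.integer(five_p),
    adapter    = rep_len(as.logical(adapter), n),
    polya_pass = rep_len(as.character(polya_pass), n),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("length_table", "data.frame")
  attr(tab, "provenance") <- provenance
  validate_length_table(tab)
}

#' Validate a length table
#'
#' Checks the structural invariants of the per-read table: required columns,
#' 0 <= five_p < three_p, `length == three_p - five_p` (hence length >= 1),
#' non-empty feature identifiers, unique (read_id, feature_id) pairs, and a
#' recognised `polya_pass` state.
#'
#' @param tab a data.frame in the canonical length-table layout.
#' @return `tab`, invisibly classed as a `length_table`.
#' @export
validate_length_table <- function(tab) {
  missing_cols <- setdiff(LT_COLUMNS, names(tab))
  if (length(missing_cols) > 0L)
    stop("length table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) {
    class(tab) <- unique(c("length_table", class(tab)))
    return(tab)
  }
  if (any(is.na(tab$five_p)) || any(is.na(tab$three_p)))
    stop("length table contains NA coordinates", call. = FALSE)
  bad <- which(tab$five_p < 0L | tab$three_p <= tab$five_p)
  if (length(bad) > 0L)
    stop("invalid coordinates (need 0 <= five_p < three_p) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(tab$length != tab$three_p - tab$five_p)
  if (length(bad) > 0L)
    stop("length != three_p - five_p at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (any(!nzchar(tab$feature_id)) || any(is.na(tab$feature_id)))
    stop("empty feature_id in length table", call. = FALSE)
  if (anyDuplicated(paste(tab$read_id, tab$feature_id, sep = "\r")))
    stop("duplicate (read_id, feature_id) pairs in length table",
         call. = FALSE)
  if (!all(tab$polya_pass %in% POLYA_LEVELS))
    stop("polya_pass must be one of: ", paste(POLYA_LEVELS, collapse = ", "),
         call. = FALSE)
  class(tab) <- unique(c("length_table", class(tab)))
  tab
}

#' @export
print.length_table <- function(x, ...) {
  cat(sprintf("length_table: %d reads, %d features, %d libraries\n",
              nrow(x), length(unique(x$feature_id)),
              length(unique(x$library_id))))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("provenance:", prov, "\n")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Read a length table from TSV
#'
#' Reads the canonical tab-separated per-read length table (as written by
#' [write_length_table()]) and validates all invariants, reporting the first
#' offending row on failure.
#'
#' @param path path to a TSV file with header columns `read_id`,
#'   `library_id`, `feature_id`, `five_p`, `three_p`, `length`, `adapter`,
#'   `polya_pass`.
#' @return A `length_table`.
#' @export
load_length_table <- function(path) {
  if (!file.exists(path))
    stop("length table file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(LT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L)
    stop("length table TSV '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, LT_COLUMNS, drop = FALSE]
  raw$five_p  <- as.integer(raw$five_p)
  raw$three_p <- as.integer(raw$three_p)
  raw$length  <- as.integer(raw$length)
  raw$adapter <- as.logical(raw$adapter)
  bad <- which(raw$length != raw$three_p - raw$five_p)
  if (length(bad) > 0L)
    stop("length != three_p - five_p at row ", bad[1L], " of ", path,
         call. = FALSE)
  attr(raw, "provenance") <- paste0("loaded from ", path)
  validate_length_table(raw)
}

#' Write a length table to TSV
#'
#' @param tab a `length_table`.
#' @param path output path; written tab-separated with a header line and no
#'   row names. Coordinates are 0-based half-open.
#' @return `path`, invisibly.
#' @export
write_length_table <- function(tab, path) {
  tab <- validate_length_table(tab)
  write.table(as.data.frame(tab)[, LT_COLUMNS, drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Append a note to a table's provenance attribute.
add_provenance <- function(tab, note) {
  prov <- attr(tab, "provenance")
  attr(tab, "provenance") <- if (is.null(prov)) note else paste(prov, note,
                                                                sep = "; ")
  tab
}
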