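#' Extract per-read aligned lengths from a transcriptome BAM/SAM
#'
#' Converts transcriptome-space alignments into the per-read length table
#' consumed by the statistical tests. Only primary, mapped alignments are
#' retained; secondary, supplementary and unmapped records are dropped, so a
#' multi-mapping read contributes a single alignment. For each retained
#' record, `five_p` is the 0-based reference alignment start and `three_p`
#' the 0-based half-open reference end, computed from the CIGAR reference
#' span. Soft-clipped bases are excluded by construction.
#'
#' @param alignments path to a BAM or SAM file of reads aligned to a
#'   transcriptome (reference names are transcript identifiers). SAM input is
#'   converted on the fly.
#' @param library_id library identifier assigned to all reads in the file
#'   (one file per sequencing library). Defaults to the file base name.
#' @param adapter_ids optional character vector of read identifiers carrying
#'   a ligated 5' adapter, or a path to a one-ID-per-line file. Reads not
#'   listed get `adapter = FALSE`; when absent every read does.
#' @return A `length_table` with one row per retained alignment. The number
#'   of records dropped by each filter is reported via `message()`.
#' @export
extract_read_lengths <- function(alignments, library_id = NULL,
                                 adapter_ids = NULL) {
  if (!file.exists(alignments))
    stop("alignment file not found: ", alignments, call. = FALSE)
  if (is.null(library_id))
    library_id <- sub("\\.(bam|sam)$", "", basename(alignments),
                      ignore.case = TRUE)
  if (is.character(adapter_ids) && length(adapter_ids) == 1L &&
      file.exists(adapter_ids))
    adapter_ids <- read_id_list(adapter_ids)

  bam_path <- as_bam(alignments)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("qname", "rname", "pos", "cigar"))
  recs <- tryCatch(
    Rsamtools::scanBam(bam_path, param = param)[[1L]],
    error = function(e) stop("failed to read alignments from '", alignments,
                             "': ", conditionMessage(e), call. = FALSE))

  n_in <- length(recs$qname)
  if (n_in == 0L) {
    message("extract_read_lengths: 0 primary mapped alignments in ",
            alignments)
    return(length_table(provenance = paste0("extracted from ", alignments)))
  }
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(recs$cigar)
  keep <- !is.na(recs$pos) & !is.na(width) & width > 0L
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("extract_read_lengths: skipped ", n_skipped,
            " alignment(s) with non-positive reference span")

  five_p <- recs$pos[keep] - 1L              # SAM POS is 1-based
  three_p <- five_p + width[keep]
  qname <- recs$qname[keep]
  adapter <- if (is.null(adapter_ids)) FALSE else qname %in% adapter_ids

  tab <- length_table(
    read_id = qname,
    library_id = library_id,
    feature_id = as.character(recs$rname[keep]),
    five_p = five_p, three_p = three_p,
    adapter = adapter,
    provenance = paste0("extracted from ", alignments,
                        " (primary mapped alignments only)"))
  message("extract_read_lengths: ", nrow(tab), " reads retained from ",
          alignments)
  tab
}

# Convert SAM to a temporary indexed BAM; pass BAM through untouched.
as_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
}

#' Read a one-identifier-per-line file
#'
#' @param path text file with one read identifier per line (used for
#'   adapter-positive read lists produced by upstream adapter trimming).
#' @return character vector of unique identifiers.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path))
    stop("read-ID list not found: ", path, call. = FALSE)
  ids <- readLines(path, warn = FALSE)
  unique(ids[nzchar(ids)])
}

#' Restrict a length table to poly(A) PASS reads
#'
#' Joins a nanopolish-style poly(A) estimation table and keeps only reads
#' whose QC tag is `"PASS"`, setting `polya_pass` accordingly. Reads absent
#' from the poly(A) table are dropped: an unknown tail status is not
#' evidence of a usable tail.
#'
#' @param tab a `length_table`.
#' @param polya a data.frame with columns `read_id` (or `readname`) and
#'   `qc_tag`, or a path to such a TSV (the nanopolish polya output dialect).
#' @return the filtered `length_table`, with `polya_pass = "pass"` on every
#'   retained row.
#' @export
join_polya_pass <- function(tab, polya) {
  tab <- validate_length_table(tab)
  if (is.character(polya)) {
    if (!file.exists(polya))
      stop("poly(A) table not found: ", polya, call. = FALSE)
    polya <- read.delim(polya, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  }
  idcol <- intersect(c("read_id", "readname"), names(polya))
  if (length(idcol) == 0L || !"qc_tag" %in% names(polya))
    stop("poly(A) table needs columns read_id/readname and qc_tag",
         call. = FALSE)
  ids <- as.character(polya[[idcol[1L]]])
  tags <- as.character(polya$qc_tag)
  if (anyDuplicated(ids)) {
    split_tags <- split(tags, ids)
    conflict <- names(split_tags)[vapply(split_tags,
                                         function(x) length(unique(x)) > 1L,
                                         logical(1L))]
    if (length(conflict) > 0L)
      stop("conflicting qc_tag values for read(s): ",
           paste(utils::head(conflict, 5L), collapse = ", "), call. = FALSE)
  }
  pass_ids <- unique(ids[tags == "PASS"])
  n_before <- nrow(tab)
  out <- tab[tab$read_id %in% pass_ids, , drop = FALSE]
  if (nrow(out) > 0L) out$polya_pass <- "pass"
  message("join_polya_pass: ", n_before - nrow(out), " of ", n_before,
          " reads dropped (no PASS poly(A) tag)")
  validate_length_table(add_provenance(out, "poly(A) PASS filter"))
}

#' Keep only reads with a ligated 5' adapter
#'
#' Adapter-ligated reads were sequenced through to their true 5' end, so
#' restricting to them removes artifactual truncations from pore ejection or
#' basecalling. Adapter status comes from the upstream read-ID list supplied
#' to [extract_read_lengths()]; this function never inspects sequence.
#'
#' @param tab a `length_table` with the `adapter` flag populated.
#' @return the `length_table` restricted to `adapter == TRUE` rows.
#' @export
filter_by_adapter <- function(tab) {
  tab <- validate_length_table(tab)
  n_before <- nrow(tab)
  out <- tab[which(tab$adapter), , drop = FALSE]
  message("filter_by_adapter: ", n_before - nrow(out), " of ", n_before,
          " reads dropped (no 5' adapter)")
  validate_length_table(add_provenance(out, "5' adapter filter"))
}

#' Drop features with insufficient reads in either condition
#'
#' A feature is retained only if it has at least `min_reads` reads in *each*
#' condition; a two-group length comparison needs observations on both
#' sides. All reads of dropped features are removed.
#'
#' @param tab a `length_table`.
#' @param design a `design_table` mapping `library_id` to `condition`.
#' @param min_reads minimum reads per feature per condition (default 5).
#' @return the filtered `length_table`.
#' @export
filter_min_reads <- function(tab, design, min_reads = 5L) {
  tab <- validate_length_table(tab)
  design <- validate_design_table(design)
  stopifnot(min_reads >= 1L)
  if (nrow(tab) == 0L) return(tab)
  unknown <- setdiff(unique(tab$library_id), design$library_id)
  if (length(unknown) > 0L)
    stop("library absent from design table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cond <- design$condition[match(tab$library_id, design$library_id)]
  counts <- table(factor(tab$feature_id),
                  factor(cond, levels = levels(design$condition)))
  ok_features <- rownames(counts)[apply(counts >= min_reads, 1L, all)]
  n_before <- nrow(tab)
  out <- tab[tab$feature_id %in% ok_features, , drop = FALSE]
  message("filter_min_reads: dropped ",
          length(unique(tab$feature_id)) - length(ok_features),
          " feature(s) (", n_before - nrow(out), " reads) below ",
          min_reads, " reads per condition")
  validate_length_table(
    add_provenance(out, sprintf("min %d reads per condition", min_reads)))
}
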