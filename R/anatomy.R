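#' Load transcript annotations
#'
#' Transcript lengths and (optionally) the 5' UTR boundary used for TSS
#' calling, from a tab-separated table or directly from a BAM header.
#'
#' @param path either a TSV with columns `feature_id`, `length` and
#'   optionally `cds_start` (transcript coordinate where the CDS begins,
#'   i.e. the 5' UTR end), or a BAM file whose `@SQ` records supply
#'   transcript lengths.
#' @return data.frame with columns `feature_id`, `length` and, when
#'   available, `cds_start`.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
    return(data.frame(feature_id = names(hdr), length = unname(hdr),
                      stringsAsFactors = FALSE))
  }
  ann <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("feature_id", "length") %in% names(ann)))
    stop("annotation TSV needs columns feature_id and length",
         call. = FALSE)
  if (any(ann$length < 1))
    stop("annotated transcript length must be >= 1", call. = FALSE)
  if ("cds_start" %in% names(ann) &&
      any(!is.na(ann$cds_start) & ann$cds_start >= ann$length))
    stop("cds_start must be smaller than transcript length", call. = FALSE)
  ann
}

#' Map read ends into the 20-bin meta-coordinate space
#'
#' Normalizes read spans across transcripts of different lengths: each
#' transcript is divided into `n_bins` (default 20) equal bins indexed
#' 0..n_bins-1, the read's 5' and 3' templated ends are assigned to bins by
#' position, and the meta-length is the spanned bin count expressed as a
#' percentage of full length. A read covering the whole transcript is
#' exactly 100%; a read inside a single bin is `100 / n_bins` percent. The
#' 3' bin is computed on the last covered base (`three_p - 1`), respecting
#' the half-open coordinate convention.
#'
#' @param five_p,three_p 0-based half-open read coordinates (vectors).
#' @param transcript_length annotated transcript length(s), recycled.
#' @param n_bins number of bins (default 20).
#' @return data.frame with columns `bin5`, `bin3` (integer, 0-based) and
#'   `meta_length_pct`.
#' @export
assign_meta_coordinates <- function(five_p, three_p, transcript_length,
                                    n_bins = 20L) {
  n <- max(length(five_p), length(three_p), length(transcript_length))
  five_p <- rep_len(as.numeric(five_p), n)
  three_p <- rep_len(as.numeric(three_p), n)
  transcript_length <- rep_len(as.numeric(transcript_length), n)
  if (any(five_p < 0 | three_p <= five_p))
    stop("need 0 <= five_p < three_p", call. = FALSE)
  if (any(three_p > transcript_length))
    stop("read end beyond annotated transcript length (",
         sum(three_p > transcript_length), " read(s))", call. = FALSE)
  bin <- function(p) pmin(floor(p * n_bins / transcript_length),
                          n_bins - 1L)
  bin5 <- bin(five_p)
  bin3 <- bin(three_p - 1)
  data.frame(bin5 = as.integer(bin5), bin3 = as.integer(bin3),
             meta_length_pct = (bin3 - bin5 + 1) * 100 / n_bins)
}

#' Mean meta-length per feature and condition
#'
#' Computes each read's meta-length percentage and averages it per feature
#' within each condition, giving the length-normalized view of transcript
#' coverage: decay-driven shortening shows up as a reduced treated-condition
#' mean independent of absolute transcript length.
#'
#' @param tab a `length_table`.
#' @param annotations data.frame from [load_annotations()] covering every
#'   feature in `tab`.
#' @param design a `design_table` mapping libraries to conditions.
#' @param min_reads features with fewer reads than this in a condition get
#'   `NA` for that condition's mean (default 5).
#' @param n_bins bins for [assign_meta_coordinates()].
#' @return data.frame with one row per feature: `feature_id`, one
#'   `mean_meta_<condition>` column per condition level, and per-condition
#'   read counts.
#' @export
summarize_metalength <- function(tab, annotations, design, min_reads = 5L,
                                 n_bins = 20L) {
  tab <- validate_length_table(tab)
  design <- validate_design_table(design)
  missing_ann <- setdiff(unique(tab$feature_id), annotations$feature_id)
  if (length(missing_ann) > 0L)
    stop("feature(s) missing from annotations: ",
         paste(utils::head(missing_ann, 5L), collapse = ", "),
         call. = FALSE)
  tl <- annotations$length[match(tab$feature_id, annotations$feature_id)]
  meta <- assign_meta_coordinates(tab$five_p, tab$three_p, tl,
                                  n_bins = n_bins)
  cond <- design$condition[match(tab$library_id, design$library_id)]
  levs <- levels(design$condition)
  agg <- lapply(levs, function(lv) {
    sel <- which(cond == lv)
    counts <- table(factor(tab$feature_id[sel]))
    means <- tapply(meta$meta_length_pct[sel],
                    factor(tab$feature_id[sel]), mean)
    data.frame(feature_id = names(means),
               mean = as.numeric(means),
               n = as.integer(counts[names(means)]),
               stringsAsFactors = FALSE)
  })
  features <- sort(unique(tab$feature_id))
  out <- data.frame(feature_id = features, stringsAsFactors = FALSE)
  for (i in seq_along(levs)) {
    m <- match(features, agg[[i]]$feature_id)
    mean_i <- agg[[i]]$mean[m]
    n_i <- agg[[i]]$n[m]
    n_i[is.na(n_i)] <- 0L
    mean_i[n_i < min_reads] <- NA_real_
    out[[paste0("mean_meta_", levs[i])]] <- mean_i
    out[[paste0("n_", levs[i])]] <- n_i
  }
  out
}

#' Call transcription start sites from read 5' end density
#'
#' Pools read 5' ends across all libraries and, within each transcript's 5'
#' UTR (positions strictly upstream of the CDS start), selects the position
#' with the highest 5'-end count as the TSS, requiring at least `min_reads`
#' supporting reads. Ties are broken toward the 5'-most (upstream)
#' position, favouring the longest plausible transcript start. Features
#' without a 5' UTR annotation are skipped (with a message); features whose
#' best position has fewer than `min_reads` supporting reads yield no call.
#'
#' @param tab a `length_table` (read 5' ends taken from `five_p`).
#' @param annotations data.frame with `feature_id`, `length` and
#'   `cds_start`.
#' @param min_reads minimum supporting reads at the called position
#'   (default 5).
#' @return data.frame with one row per called feature: `feature_id`,
#'   `tss_position` (0-based transcript coordinate), `support`.
#' @export
identify_tss <- function(tab, annotations, min_reads = 5L) {
  tab <- validate_length_table(tab)
  if (!"cds_start" %in% names(annotations))
    stop("annotations need a cds_start column for TSS calling",
         call. = FALSE)
  ann <- annotations[!is.na(annotations$cds_start), , drop = FALSE]
  skipped <- setdiff(unique(tab$feature_id), ann$feature_id)
  if (length(skipped) > 0L)
    message("identify_tss: skipping ", length(skipped),
            " feature(s) without 5' UTR annotation")
  calls <- lapply(intersect(unique(tab$feature_id), ann$feature_id),
                  function(fid) {
    cds <- ann$cds_start[ann$feature_id == fid][1L]
    ends <- tab$five_p[tab$feature_id == fid]
    ends <- ends[ends < cds]           # restrict to the 5' UTR
    if (length(ends) == 0L) return(NULL)
    counts <- table(ends)
    best <- max(counts)
    if (best < min_reads) return(NULL)
    pos <- min(as.integer(names(counts)[counts == best]))  # 5'-most tie
    data.frame(feature_id = fid, tss_position = pos,
               support = as.integer(best), stringsAsFactors = FALSE)
  })
  calls <- calls[!vapply(calls, is.null, logical(1L))]
  if (length(calls) == 0L)
    return(data.frame(feature_id = character(), tss_position = integer(),
                      support = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Nucleotide composition around read 5' ends
#'
#' For every read, looks up the reference transcript bases at fixed offsets
#' around the 5' templated end (offset 0 = the first aligned base) and
#' tallies A/C/G/T frequencies per offset. Offsets falling outside the
#' transcript are skipped, not padded, so per-offset totals shrink near
#' transcript boundaries. Uracil is reported as T.
#'
#' @param tab a `length_table`.
#' @param sequences transcript sequences: a `Biostrings::DNAStringSet`, or
#'   a path to a FASTA file. Names must match `feature_id`s.
#' @param window integer vector of length 2, offsets relative to the 5' end
#'   (default `c(-10, 10)`).
#' @return list of class `"composition_matrix"` with elements `offsets`,
#'   `freq` (matrix offsets x ACGT, rows summing to 1 where counted),
#'   `counts` (raw tallies) and `total` (bases counted per offset).
#' @export
nucleotide_composition <- function(tab, sequences, window = c(-10L, 10L)) {
  tab <- validate_length_table(tab)
  stopifnot(length(window) == 2L, window[1L] <= window[2L],
            all(is.finite(window)))
  if (is.character(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  stopifnot(methods::is(sequences, "DNAStringSet"))
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  missing_seq <- setdiff(unique(tab$feature_id), names(sequences))
  if (length(missing_seq) > 0L)
    stop("feature missing from FASTA: ", missing_seq[1L], call. = FALSE)

  offsets <- seq(window[1L], window[2L])
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = length(offsets), ncol = length(bases),
                   dimnames = list(offsets, bases))
  seq_len_of <- setNames(Biostrings::width(sequences), names(sequences))
  tlen <- seq_len_of[tab$feature_id]
  chars <- as.character(sequences)
  for (i in seq_along(offsets)) {
    pos <- tab$five_p + offsets[i]          # 0-based position
    ok <- pos >= 0L & pos < tlen
    if (!any(ok)) next
    b <- substring(chars[tab$feature_id[ok]], pos[ok] + 1L, pos[ok] + 1L)
    b <- chartr("u", "t", chartr("U", "T", toupper(b)))
    tb <- table(factor(b, levels = bases))
    counts[i, ] <- counts[i, ] + as.integer(tb)
  }
  total <- rowSums(counts)
  freq <- counts / ifelse(total > 0, total, 1)
  structure(list(offsets = offsets, freq = freq, counts = counts,
                 total = total),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("nucleotide composition around read 5' ends, offsets",
      min(x$offsets), "..", max(x$offsets), "\n")
  print(round(x$freq, 3))
  invisible(x)
}
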