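#' Describe a synthetic alignment fixture
#'
#' Defines a small, fully known dataset emulating a stressed-versus-control
#' nanopore experiment: a set of transcripts, a library design, and a
#' per-condition 5' truncation distribution. Reads are 3'-anchored (they
#' end at the annotated 3' end, as poly(A)-primed direct RNA reads do) and
#' lose a random fraction of the transcript from the 5' end, so the treated
#' condition's truncation mean directly sets the expected length deficit.
#'
#' @param features data.frame with `feature_id`, `length` (nt) and
#'   optionally `cds_start`.
#' @param libraries data.frame with `library_id`, `condition`.
#' @param count reads per feature per library.
#' @param trunc_frac named numeric: mean truncated fraction of transcript
#'   length per condition (names = condition levels), each in \[0, 1).
#' @param trunc_sd_frac SD of the per-read truncated fraction.
#' @param adapter_prob probability that a read is 5'-adapter flagged.
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(features, libraries, count = 50L,
                         trunc_frac = c(control = 0.02, treated = 0.30),
                         trunc_sd_frac = 0.03, adapter_prob = 1) {
  stopifnot(all(c("feature_id", "length") %in% names(features)),
            all(c("library_id", "condition") %in% names(libraries)),
            count >= 1, trunc_sd_frac >= 0,
            adapter_prob >= 0, adapter_prob <= 1)
  conds <- unique(as.character(libraries$condition))
  if (!all(conds %in% names(trunc_frac)))
    stop("trunc_frac must name every condition: ",
         paste(conds, collapse = ", "), call. = FALSE)
  if (any(trunc_frac < 0 | trunc_frac >= 1))
    stop("trunc_frac must lie in [0, 1): a read span cannot exceed the ",
         "transcript length", call. = FALSE)
  if (any(features$length < 1))
    stop("feature length must be >= 1", call. = FALSE)
  structure(list(features = features, libraries = libraries,
                 count = as.integer(count), trunc_frac = trunc_frac,
                 trunc_sd_frac = trunc_sd_frac,
                 adapter_prob = adapter_prob),
            class = "fixture_spec")
}

#' Default fixture: six transcripts, three control + three treated libraries
#'
#' @param count reads per feature per library (default 50).
#' @param treated_trunc mean treated 5' truncation fraction (default 0.30,
#'   i.e. a 30% length deficit).
#' @return a [fixture_spec()].
#' @export
default_fixture_spec <- function(count = 50L, treated_trunc = 0.30) {
  features <- data.frame(
    feature_id = sprintf("tx_%02d", 1:6),
    length = c(1200L, 2000L, 3000L, 1500L, 800L, 2400L),
    cds_start = c(150L, 300L, 450L, 200L, 100L, 350L))
  libraries <- data.frame(
    library_id = c("ctrl_1", "ctrl_2", "ctrl_3",
                   "trt_1", "trt_2", "trt_3"),
    condition = rep(c("control", "treated"), each = 3L))
  fixture_spec(features, libraries, count = count,
               trunc_frac = c(control = 0.02, treated = treated_trunc))
}

# Temporarily seed the global RNG, restoring the caller's state on exit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate synthetic alignment fixtures with known truth
#'
#' Writes a complete synthetic dataset realizing a [fixture_spec()]:
#' per-library indexed transcriptome BAM files (via an intermediate SAM),
#' the transcript FASTA (random sequence) with index, an annotation TSV, a
#' library metadata TSV, an adapter-positive read-ID list, and a truth TSV
#' recording every read's intended span. `extract_read_lengths()` on the
#' emitted BAMs reproduces the truth table record for record, which is the
#' round-trip property the end-to-end tests rely on.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @return invisibly, a list of generated paths: `bam` (named by library),
#'   `fasta`, `annotation`, `metadata`, `adapter_ids`, `truth`.
#' @export
generate_fixtures <- function(spec, out_dir, seed = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    feats <- spec$features
    libs <- spec$libraries

    # transcript sequences
    seqs <- vapply(feats$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1L))
    names(seqs) <- feats$feature_id
    fasta <- file.path(out_dir, "transcripts.fa")
    writeLines(paste0(">", feats$feature_id, "\n", seqs), fasta)
    Rsamtools::indexFa(fasta)

    # reads: 3'-anchored with per-condition 5' truncation
    truth <- list()
    bam_paths <- character(0L)
    for (li in seq_len(nrow(libs))) {
      lib <- libs$library_id[li]
      cond <- as.character(libs$condition[li])
      recs <- list()
      for (fi in seq_len(nrow(feats))) {
        L <- feats$length[fi]
        frac <- pmin(pmax(rnorm(spec$count, spec$trunc_frac[[cond]],
                                spec$trunc_sd_frac), 0), 1 - 1 / L)
        five_p <- as.integer(floor(frac * L))
        three_p <- rep(L, spec$count)
        recs[[fi]] <- data.frame(
          read_id = sprintf("%s.%s.r%03d", lib, feats$feature_id[fi],
                            seq_len(spec$count)),
          library_id = lib,
          feature_id = feats$feature_id[fi],
          five_p = five_p, three_p = three_p,
          length = three_p - five_p,
          adapter = stats::runif(spec$count) < spec$adapter_prob,
          stringsAsFactors = FALSE)
      }
      lib_truth <- do.call(rbind, recs)
      truth[[lib]] <- lib_truth

      sam <- file.path(out_dir, paste0(lib, ".sam"))
      hdr <- c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", feats$feature_id,
                       feats$length))
      body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                      lib_truth$read_id, lib_truth$feature_id,
                      lib_truth$five_p + 1L, lib_truth$length,
                      substring(seqs[lib_truth$feature_id],
                                lib_truth$five_p + 1L, lib_truth$three_p))
      writeLines(c(hdr, body), sam)
      bam <- Rsamtools::asBam(sam, file.path(out_dir, lib),
                              overwrite = TRUE, indexDestination = TRUE)
      bam_paths[lib] <- bam
    }

    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    truth_path <- file.path(out_dir, "truth.tsv")
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    adapter_path <- file.path(out_dir, "adapter_ids.txt")
    writeLines(truth$read_id[truth$adapter], adapter_path)

    ann_path <- file.path(out_dir, "annotation.tsv")
    write.table(feats, ann_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    meta_path <- file.path(out_dir, "metadata.tsv")
    write.table(libs, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    invisible(list(bam = bam_paths, fasta = fasta, annotation = ann_path,
                   metadata = meta_path, adapter_ids = adapter_path,
                   truth = truth_path))
  })
}

#' Ingest every library of a generated fixture
#'
#' Convenience wrapper running [extract_read_lengths()] on each per-library
#' BAM of a [generate_fixtures()] output and binding the results.
#'
#' @param paths the path list returned by [generate_fixtures()].
#' @param adapter_ids use the fixture's adapter list (default `TRUE`).
#' @return a `length_table` covering all libraries.
#' @export
ingest_fixtures <- function(paths, adapter_ids = TRUE) {
  ids <- if (adapter_ids) read_id_list(paths$adapter_ids) else NULL
  tabs <- lapply(names(paths$bam), function(lib)
    extract_read_lengths(paths$bam[[lib]], library_id = lib,
                         adapter_ids = ids))
  out <- do.call(rbind, tabs)
  validate_length_table(out)
}
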