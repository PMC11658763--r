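test_that("meta-coordinates map reads into the 20-bin space", {
  # full-length read: bins (0, 19), exactly 100% of full length
  mc <- assign_meta_coordinates(0L, 2000L, 2000L)
  expect_equal(mc$bin5, 0L)
  expect_equal(mc$bin3, 19L)
  expect_equal(mc$meta_length_pct, 100)

  # 3' half of the transcript: bins (10, 19), 50%
  mc <- assign_meta_coordinates(500L, 1000L, 1000L)
  expect_equal(mc$bin5, 10L)
  expect_equal(mc$bin3, 19L)
  expect_equal(mc$meta_length_pct, 50)

  # single-base read occupies one bin: 5%
  mc <- assign_meta_coordinates(0L, 1L, 1000L)
  expect_equal(mc$meta_length_pct, 5)

  expect_error(assign_meta_coordinates(100L, 1200L, 1000L), "beyond")
  expect_error(assign_meta_coordinates(10L, 10L, 1000L), "five_p")
})

test_that("bin assignment equals a brute-force boundary scan", {
  set.seed(61)
  n <- 10000L
  L <- sample(c(97L, 500L, 1000L, 2037L, 60000L), n, replace = TRUE)
  five_p <- floor(runif(n) * (L - 1))
  three_p <- five_p + 1 + floor(runif(n) * (L - five_p - 1))
  mc <- assign_meta_coordinates(five_p, three_p, L)
  idx <- sample(n, 500L)            # oracle is O(bins) per lookup
  for (i in idx) {
    expect_identical(mc$bin5[i], oracle_bin(five_p[i], L[i]))
    expect_identical(mc$bin3[i], oracle_bin(three_p[i] - 1, L[i]))
  }
  # structural invariants over all 10^4 reads
  expect_true(all(mc$bin5 >= 0L & mc$bin3 <= 19L))
  expect_true(all(mc$bin5 <= mc$bin3))
  expect_true(all(mc$meta_length_pct >= 5 & mc$meta_length_pct <= 100))
  expect_true(all(mc$meta_length_pct %% 5 == 0))
})

test_that("meta-length is invariant under joint coordinate scaling", {
  set.seed(62)
  L <- 700L
  five_p <- sample(0:(L - 2L), 200L, replace = TRUE)
  three_p <- five_p + sample(1:100, 200L, replace = TRUE)
  three_p <- pmin(three_p, L)
  a <- assign_meta_coordinates(five_p, three_p, L)
  # scale the end positions: 5' start and last covered base
  b <- assign_meta_coordinates(3L * five_p, 3L * (three_p - 1L) + 1L,
                               3L * L)
  expect_equal(a$meta_length_pct, b$meta_length_pct)
})

test_that("per-condition meta-length means reflect read spans", {
  design <- suppressWarnings(
    design_table(c("c1", "t1"), c("control", "treated"),
                 reference = "control"))
  ann <- data.frame(feature_id = c("x", "y"), length = c(1000L, 600L))
  full_and_half <- length_table(
    read_id = sprintf("r%02d", 1:20),
    library_id = rep(c("c1", "t1"), each = 10L),
    feature_id = rep(rep(c("x", "y"), each = 5L), 2L),
    five_p = rep(c(0L, 0L, 500L, 300L), each = 5L),
    three_p = rep(c(1000L, 600L, 1000L, 600L), each = 5L))
  out <- summarize_metalength(full_and_half, ann, design, min_reads = 5L)
  expect_equal(out$mean_meta_control, c(100, 100))
  expect_equal(out$mean_meta_treated, c(50, 50))

  # below min reads in one condition: that mean is withheld
  sparse <- full_and_half[c(1:10, 11:13), ]
  out2 <- summarize_metalength(sparse, ann, design, min_reads = 5L)
  expect_true(is.na(out2$mean_meta_treated[out2$feature_id == "x"]))

  expect_error(
    summarize_metalength(full_and_half, ann[1L, ], design),
    "missing from annotations")
})

test_that("TSS calls equal the brute-force histogram argmax", {
  ann <- data.frame(feature_id = "tx", length = 1000L, cds_start = 100L)
  mk <- function(five_p) length_table(
    read_id = sprintf("r%03d", seq_along(five_p)),
    library_id = "lib1", feature_id = "tx",
    five_p = as.integer(five_p), three_p = 900L)

  # argmax with support over the threshold
  calls <- identify_tss(mk(c(10, 10, 10, 10, 10, 12)), ann)
  expect_equal(calls$tss_position, 10L)
  expect_equal(calls$support, 5L)

  # four supporting reads only: no call
  expect_equal(nrow(identify_tss(mk(c(10, 10, 10, 10)), ann)), 0L)

  # tie broken toward the 5'-most position
  tie <- identify_tss(mk(rep(c(20L, 10L), each = 5L)), ann)
  expect_equal(tie$tss_position, 10L)

  # reads outside the 5' UTR are ignored
  none <- identify_tss(mk(rep(150L, 10L)), ann)
  expect_equal(nrow(none), 0L)

  # feature without UTR annotation is skipped with a message
  no_utr <- data.frame(feature_id = "tx", length = 1000L,
                       cds_start = NA_integer_)
  expect_message(out <- identify_tss(mk(rep(5L, 6L)), no_utr),
                 "without 5' UTR")
  expect_equal(nrow(out), 0L)

  # randomized features against the oracle
  set.seed(63)
  for (i in 1:40) {
    fp <- sample(0:199, sample(3:60, 1L), replace = TRUE)
    got <- identify_tss(mk(fp), ann)
    want <- oracle_tss(fp, 100L)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$tss_position, want$pos)
      expect_equal(got$support, want$support)
    }
  }
})

test_that("5'-end composition counts reference bases per offset", {
  seqs <- Biostrings::DNAStringSet(c(tx = "AAAAAGTTTT"))
  one <- length_table(read_id = "r1", library_id = "l1",
                      feature_id = "tx", five_p = 5L, three_p = 10L)
  comp <- nucleotide_composition(one, seqs, window = c(-1L, 1L))
  expect_equal(comp$freq["-1", "A"], 1)
  expect_equal(comp$freq["0", "G"], 1)
  expect_equal(comp$freq["1", "T"], 1)

  # 5' end at the transcript start: negative offsets count nothing
  edge <- length_table(read_id = "r1", library_id = "l1",
                       feature_id = "tx", five_p = 0L, three_p = 10L)
  comp_e <- nucleotide_composition(edge, seqs, window = c(-2L, 0L))
  expect_equal(unname(comp_e$total[c("-2", "-1")]), c(0L, 0L))
  expect_equal(unname(comp_e$total["0"]), 1L)

  expect_error(
    nucleotide_composition(one, Biostrings::DNAStringSet(c(zz = "ACGT"))),
    "missing from FASTA")
})

test_that("composition frequencies normalize and conserve reads", {
  set.seed(64)
  L <- 300L
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
      character(1L)),
    paste0("tx", 1:4)))
  n <- 1000L
  five_p <- sample(0:(L - 20L), n, replace = TRUE)
  tab <- length_table(read_id = sprintf("r%04d", 1:n),
                      library_id = "l1",
                      feature_id = sample(paste0("tx", 1:4), n, TRUE),
                      five_p = five_p, three_p = five_p + 15L)
  comp <- nucleotide_composition(tab, seqs, window = c(-10L, 10L))
  sums <- rowSums(comp$freq)[comp$total > 0]
  expect_true(all(abs(sums - 1) < 1e-9))
  # offset 0 counts every read whose 5' end lies inside its transcript
  expect_equal(unname(comp$total["0"]), n)

  # per-base counting oracle at one offset
  off <- 3L
  base_at <- substring(as.character(seqs)[tab$feature_id],
                       tab$five_p + off + 1L, tab$five_p + off + 1L)
  expect_equal(unname(comp$counts[as.character(off), ]),
               as.integer(table(factor(base_at,
                                       levels = c("A", "C", "G", "T")))))
})
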