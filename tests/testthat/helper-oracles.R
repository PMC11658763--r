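# Independent reference implementations used to cross-check the package.
# These deliberately use first-principles formulas or brute-force
# enumeration, not the code paths they validate.

# Closed-form pooled-variance two-sample t-test.
oracle_ttest <- function(y0, y1) {
  n0 <- length(y0); n1 <- length(y1)
  est <- mean(y1) - mean(y0)
  sp2 <- ((n0 - 1) * var(y0) + (n1 - 1) * var(y1)) / (n0 + n1 - 2)
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  tval <- est / se
  list(estimate = est, se = se, statistic = tval,
       p_value = 2 * pt(-abs(tval), df = n0 + n1 - 2))
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n0+n1, n1) rank assignments (no ties assumed).
oracle_wilcoxon_exact <- function(y0, y1) {
  n0 <- length(y0); n1 <- length(y1)
  ranks <- rank(c(y0, y1))
  w_obs <- sum(ranks[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(combn(n0 + n1, n1), 2L,
                 function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs))
  min(1, p)
}

# Hand-applied Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force bin lookup: scan all bin boundaries for the bin containing a
# 0-based position on a transcript of length L.
oracle_bin <- function(pos, L, n_bins = 20L) {
  for (b in seq_len(n_bins) - 1L) {
    lo <- b * L / n_bins
    hi <- (b + 1) * L / n_bins
    if (pos >= lo && (pos < hi || b == n_bins - 1L)) return(b)
  }
  stop("position outside transcript")
}

# Brute-force TSS: histogram argmax within the 5' UTR, 5'-most tie-break,
# minimum support.
oracle_tss <- function(five_p, cds_start, min_reads = 5L) {
  utr <- five_p[five_p < cds_start]
  if (length(utr) == 0L) return(NULL)
  counts <- table(utr)
  best <- max(counts)
  if (best < min_reads) return(NULL)
  list(pos = min(as.integer(names(counts)[counts == best])),
       support = as.integer(best))
}

# Small in-code length table shared across tests.
make_toy_table <- function() {
  length_table(
    read_id = sprintf("r%02d", 1:8),
    library_id = rep(c("libA", "libB"), each = 4L),
    feature_id = rep(c("tx1", "tx2"), 4L),
    five_p = c(0L, 10L, 5L, 0L, 100L, 50L, 0L, 25L),
    three_p = c(300L, 410L, 250L, 90L, 400L, 480L, 220L, 325L),
    adapter = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
    polya_pass = "unknown")
}

# Write a small SAM file from a record data.frame (five_p 0-based).
write_toy_sam <- function(path, targets, recs) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets),
                   unname(targets)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                  recs$read_id, recs$flag, recs$feature_id,
                  recs$five_p + 1L, recs$three_p - recs$five_p,
                  strrep("A", recs$three_p - recs$five_p))
  writeLines(c(hdr, body), path)
  path
}
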