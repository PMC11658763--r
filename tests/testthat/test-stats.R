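test_that("t-test equals the closed-form pooled-variance t", {
  # spec'd toy case
  fit <- fit_ttest(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(fit$estimate, 2)
  expect_equal(fit$statistic, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(fit$df, 2)
  expect_equal(fit$p_value, oracle_ttest(c(1, 2), c(3, 4))$p_value,
               tolerance = 1e-12)

  # identical samples: no effect, p = 1
  fit0 <- fit_ttest(c(1, 3, 1, 3), c(0, 0, 1, 1))
  expect_equal(fit0$estimate, 0)
  expect_equal(fit0$statistic, 0)
  expect_equal(fit0$p_value, 1)

  # sign convention: shorter treated lengths give negative estimates
  fitn <- fit_ttest(c(10, 12, 6, 8), c(0, 0, 1, 1))
  expect_equal(fitn$estimate, -4)

  # random vectors agree with the oracle to 1e-10
  set.seed(101)
  for (i in 1:25) {
    n0 <- sample(3:30, 1L); n1 <- sample(3:30, 1L)
    y0 <- rnorm(n0, 100, 20); y1 <- rnorm(n1, 95, 25)
    fit <- fit_ttest(c(y0, y1), rep(c(0, 1), c(n0, n1)))
    orc <- oracle_ttest(y0, y1)
    expect_equal(fit$estimate, orc$estimate, tolerance = 1e-10)
    expect_equal(fit$se, orc$se, tolerance = 1e-10)
    expect_equal(fit$statistic, orc$statistic, tolerance = 1e-10)
    expect_equal(fit$p_value, orc$p_value, tolerance = 1e-10)
  }
})

test_that("t-test rejects degenerate inputs rather than fabricating p", {
  expect_error(fit_ttest(c(1, 2, 3), c(0, 0, 1)), "insufficient")
  expect_error(fit_ttest(c(5, 5, 5, 5), c(0, 0, 1, 1)),
               "zero residual variance")
})

test_that("Wilcoxon matches exhaustive rank enumeration and handles ties", {
  f1 <- fit_wilcoxon(c(1, 2, 3, 4, 5, 6), rep(c(0, 1), each = 3L))
  expect_equal(f1$p_value, 0.1)
  expect_equal(f1$p_value, oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)))

  f2 <- fit_wilcoxon(c(1, 3, 5, 2, 4, 6), rep(c(0, 1), each = 3L))
  expect_equal(f2$p_value, 0.7)
  expect_equal(f2$p_value, oracle_wilcoxon_exact(c(1, 3, 5), c(2, 4, 6)))

  set.seed(202)
  for (i in 1:20) {
    n0 <- sample(2:6, 1L); n1 <- sample(2:6, 1L)
    y <- sample(1000L, n0 + n1)           # distinct values: no ties
    fit <- fit_wilcoxon(y, rep(c(0, 1), c(n0, n1)))
    expect_equal(fit$p_value,
                 oracle_wilcoxon_exact(y[1:n0], y[-(1:n0)]),
                 tolerance = 1e-12)
  }

  # full ties: no separation, p = 1 under the corrected approximation
  ft <- fit_wilcoxon(rep(7, 6), rep(c(0, 1), each = 3L))
  expect_equal(ft$p_value, 1)
  expect_equal(ft$estimate, 0)

  expect_error(fit_wilcoxon(c(1, 2), c(0, 0)), "insufficient")
})

test_that("mixed model recovers the balanced-design library-mean contrast", {
  set.seed(303)
  n <- 50L
  lib_means <- c(100, 102, 90, 92)
  y <- unlist(lapply(lib_means, function(m) rnorm(n, m, 1)))
  lib <- rep(paste0("L", 1:4), each = n)
  cond <- rep(c(0, 1), each = 2L * n)
  fit <- fit_lmm(y, cond, lib)
  # balanced design: beta equals the difference of condition means of
  # library means, whatever the variance components
  per_lib <- tapply(y, lib, mean)[paste0("L", 1:4)]
  expect_equal(fit$estimate, mean(per_lib[3:4]) - mean(per_lib[1:2]),
               tolerance = 1e-6)
  expect_equal(fit$estimate, -10, tolerance = 1)
  expect_named(fit$variance_components, c("lib", "resid"))
})

test_that("zero library variance degenerates the mixed model to OLS", {
  set.seed(304)
  y <- rnorm(120, 500, 40)
  cond <- rep(c(0, 1), each = 60L)
  lib <- rep(paste0("L", 1:6), each = 20L)   # no simulated lib effect
  fit_m <- fit_lmm(y, cond, lib)
  fit_t <- fit_ttest(y, cond)
  if (fit_m$status == "singular_fallback") {
    expect_equal(fit_m$estimate, fit_t$estimate, tolerance = 1e-6)
    expect_equal(fit_m$p_value, fit_t$p_value, tolerance = 1e-6)
    expect_equal(unname(fit_m$variance_components["lib"]), 0)
  } else {
    # tiny estimated library variance: estimates still agree closely
    expect_equal(fit_m$estimate, fit_t$estimate, tolerance = 1e-3)
  }
})

test_that("log-scale estimates are invariant to length rescaling", {
  set.seed(305)
  n <- 30L
  y <- exp(rnorm(6 * n, log(800), 0.2))
  cond <- rep(c(0, 1), each = 3L * n)
  lib <- rep(paste0("L", 1:6), each = n)
  f1 <- fit_lmm(log2(y), cond, lib)
  f2 <- fit_lmm(log2(2 * y), cond, lib)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
  # raw-scale equivariance: shift leaves the estimate alone, scale
  # multiplies it
  g1 <- fit_ttest(y, cond)
  expect_equal(fit_ttest(y + 100, cond)$estimate, g1$estimate,
               tolerance = 1e-9)
  expect_equal(fit_ttest(3 * y, cond)$estimate, 3 * g1$estimate,
               tolerance = 1e-9)
})

test_that("mixed-model input validation catches structural problems", {
  y <- rnorm(40)
  expect_error(fit_lmm(y, rep(c(0, 1), each = 20L), rep("L1", 40L)),
               "2 libraries")
  # library spanning both conditions violates nesting
  expect_error(
    fit_lmm(y, rep(c(0, 1), each = 20L),
            rep(c("L1", "L2", "L1", "L3"), each = 10L)),
    "nested")
  expect_warning(
    fit_lmm(y, rep(c(0, 1), each = 20L),
            rep(c("L1", "L2"), each = 20L)),
    "confounded")
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.5), 0.5)
  expect_equal(adjust_pvalues(c(1, 1, 1)), c(1, 1, 1))

  set.seed(404)
  p <- runif(50)
  expect_equal(adjust_pvalues(p), oracle_bh(p), tolerance = 1e-12)
  expect_true(all(adjust_pvalues(p) >= p))
  # permutation equivariance
  perm <- sample(50L)
  expect_equal(adjust_pvalues(p[perm]), adjust_pvalues(p)[perm])
  # bonferroni alternative
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"),
               c(0.02, 0.8))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("config rejects covariates under the Wilcoxon model", {
  expect_error(test_config("wilcoxon", covariates = "batch"),
               "condition variable only")
  expect_error(test_config(alpha = 0), "alpha")
})

test_that("per-feature run tests every feature and sorts by p-value", {
  set.seed(505)
  design <- design_table(paste0("L", 1:6),
                         rep(c("control", "treated"), each = 3L),
                         reference = "control")
  n <- 20L
  mk_feature <- function(fid, shift) {
    mu <- ifelse(rep(c(0, 1), each = 3L * n) == 1, 1000 - shift, 1000)
    len <- pmax(1L, as.integer(round(rnorm(6 * n, mu, 80))))
    length_table(read_id = paste0(fid, "_", seq_len(6 * n)),
                 library_id = rep(paste0("L", 1:6), each = n),
                 feature_id = fid, five_p = 0L, three_p = len)
  }
  tab <- rbind(mk_feature("null1", 0), mk_feature("shift", 400),
               mk_feature("null2", 0))
  res <- suppressMessages(
    run_differential_length(tab, design, test_config("lmm")))
  expect_equal(nrow(res), 3L)
  expect_equal(res$feature_id[1L], "shift")
  expect_lt(res$estimate[1L], 0)
  expect_true(!is.unsorted(res$p_value))
  expect_true(all(res$adj_p_value >= res$p_value))
  expect_equal(res$n_control, rep(3L * n, 3L))

  # exactly equal conditions per library: estimate 0
  len <- rep(c(500L, 600L, 700L), 4L)
  eq <- length_table(read_id = paste0("e", 1:12),
                     library_id = rep(paste0("L", 1:4), each = 3L),
                     feature_id = "flat", five_p = 0L, three_p = len)
  des4 <- design_table(paste0("L", 1:4),
                       rep(c("control", "treated"), each = 2L),
                       reference = "control")
  res_eq <- suppressMessages(
    run_differential_length(eq, des4, test_config("ttest")))
  expect_equal(res_eq$estimate, 0)

  # single feature: BH with m = 1 leaves p unchanged
  res1 <- suppressMessages(
    run_differential_length(mk_feature("only", 100), design,
                            test_config("ttest")))
  expect_equal(res1$adj_p_value, res1$p_value)

  # failing features are flagged, not dropped
  tiny <- length_table(read_id = c("t1", "t2"),
                       library_id = c("L1", "L4"),
                       feature_id = "tiny", five_p = 0L,
                       three_p = c(400L, 500L))
  res2 <- suppressMessages(run_differential_length(
    rbind(mk_feature("good", 300), tiny), design,
    test_config("ttest")))
  expect_equal(nrow(res2), 2L)
  expect_true(all(c("good", "tiny") %in% res2$feature_id))
  expect_match(res2$status[res2$feature_id == "tiny"], "failed")
  expect_false(is.na(res2$adj_p_value[res2$feature_id == "good"]))

  # empty table warns and returns an empty result
  expect_warning(res0 <- run_differential_length(tab[0L, ], design,
                                                 test_config("ttest")),
                 "no features")
  expect_equal(nrow(res0), 0L)
})
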