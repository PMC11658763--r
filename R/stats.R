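#' @importFrom stats lm pnorm pt p.adjust median coef wilcox.test as.formula
NULL

# Normalize a condition vector to 0 (control) / 1 (treated).
# Accepts logical, 0/1 numeric, or a 2-level factor with the reference
# (control) level first.
as_binary_condition <- function(condition) {
  if (is.factor(condition)) {
    if (nlevels(condition) != 2L)
      stop("condition must have exactly 2 levels", call. = FALSE)
    return(as.integer(condition) - 1L)
  }
  if (is.logical(condition)) return(as.integer(condition))
  u <- unique(condition)
  if (!all(u %in% c(0, 1)))
    stop("condition must be binary (0 = control, 1 = treated)",
         call. = FALSE)
  as.integer(condition)
}

#' Two-sample location test via linear regression
#'
#' Fits ordinary least squares of read length on an intercept and the
#' condition indicator (plus optional read-level covariates). With no
#' covariates this is exactly the pooled-variance two-sample t-test; the
#' condition coefficient is the difference of condition means and its
#' two-sided p-value comes from the t distribution with residual degrees of
#' freedom. Note that reads from the same library are treated as
#' independent, so this model is anticonservative when libraries shift
#' lengths jointly — that is what the mixed model in [fit_lmm()] corrects.
#'
#' @param lengths numeric vector of read lengths (log2-transformed upstream
#'   when testing fold changes).
#' @param condition binary vector (0 = control, 1 = treated), logical, or a
#'   two-level factor with the control level first.
#' @param covariates optional data.frame of read-level covariates.
#' @return list with `estimate` (treated minus control), `se`, `statistic`
#'   (t), `df`, `p_value`, and `status = "ok"`.
#' @export
fit_ttest <- function(lengths, condition, covariates = NULL) {
  cond <- as_binary_condition(condition)
  stopifnot(length(lengths) == length(cond))
  if (sum(cond == 0L) < 2L || sum(cond == 1L) < 2L)
    stop("insufficient data: need at least 2 observations per condition",
         call. = FALSE)
  dat <- data.frame(.y = lengths, .cond = cond)
  form <- .y ~ .cond
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    stopifnot(nrow(covariates) == length(lengths))
    dat <- cbind(dat, covariates)
    form <- as.formula(paste(".y ~ .cond +",
                             paste(names(covariates), collapse = " + ")))
  }
  fit <- lm(form, data = dat)
  cf <- suppressWarnings(summary(fit))$coefficients
  if (!is.finite(cf[".cond", "Std. Error"]) ||
      cf[".cond", "Std. Error"] == 0)
    stop("undefined statistic: zero residual variance", call. = FALSE)
  list(estimate = unname(cf[".cond", "Estimate"]),
       se = unname(cf[".cond", "Std. Error"]),
       statistic = unname(cf[".cond", "t value"]),
       df = fit$df.residual,
       p_value = unname(cf[".cond", "Pr(>|t|)"]),
       status = "ok")
}

#' Wilcoxon rank-sum test of read lengths between conditions
#'
#' Two-sided Mann-Whitney test of the condition variable only (no
#' covariates). Uses the exact rank-sum distribution when both groups have
#' fewer than 50 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. The reported estimate
#' is the descriptive difference of group medians (treated minus control);
#' the test itself is rank-based.
#'
#' @inheritParams fit_ttest
#' @return list with `estimate` (median difference), `statistic` (W for the
#'   treated group), `p_value`, and `status = "ok"`.
#' @export
fit_wilcoxon <- function(lengths, condition) {
  cond <- as_binary_condition(condition)
  stopifnot(length(lengths) == length(cond))
  y0 <- lengths[cond == 0L]
  y1 <- lengths[cond == 1L]
  if (length(y0) < 1L || length(y1) < 1L)
    stop("insufficient data: need at least 1 observation per condition",
         call. = FALSE)
  wt <- suppressWarnings(wilcox.test(y1, y0, alternative = "two.sided",
                                     correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # all observations tied: no evidence either way
  list(estimate = median(y1) - median(y0),
       statistic = unname(wt$statistic),
       p_value = p,
       status = "ok")
}

#' Linear mixed model test with a library random effect
#'
#' The core differential-length model: read length is regressed on the
#' condition fixed effect with a random intercept per sequencing library,
#' \deqn{Y = \beta_0 + \beta_{cond} \cdot cond + u_{lib} + \epsilon,}
#' so replicate-to-replicate length shifts are absorbed by the random effect
#' instead of inflating the condition effect, and deeper libraries cannot
#' dominate the estimate. Significance of \eqn{\beta_{cond}} is assessed by
#' a Wald test on the fitted coefficient; with only a handful of libraries
#' the reference distribution matters, so the default uses the Satterthwaite
#' degrees-of-freedom approximation under REML, which holds the type-I error
#' at its nominal level in simulation (a normal reference is available via
#' `df_method = "normal"`, and is markedly anticonservative with 3+3
#' libraries).
#'
#' If the random-effect variance is estimated as zero (singular fit) or the
#' fit fails, the model degenerates to the fixed-effects regression of
#' [fit_ttest()] and the result is flagged `status = "singular_fallback"`.
#'
#' @inheritParams fit_ttest
#' @param library_ids vector identifying the sequencing library of each
#'   read; libraries must be nested within condition.
#' @param covariates optional data.frame of read-level covariates (fixed
#'   effects).
#' @param reml logical, fit by REML (default) or maximum likelihood.
#' @param df_method `"satterthwaite"` (default) or `"normal"` reference for
#'   the Wald p-value.
#' @return list with `estimate`, `se`, `statistic`, `df` (NA for the normal
#'   reference), `p_value`, `variance_components` (named vector: `lib`,
#'   `resid`), and `status`.
#' @export
fit_lmm <- function(lengths, condition, library_ids, covariates = NULL,
                    reml = TRUE, df_method = c("satterthwaite", "normal")) {
  df_method <- match.arg(df_method)
  cond <- as_binary_condition(condition)
  stopifnot(length(lengths) == length(cond),
            length(library_ids) == length(cond))
  lib <- factor(library_ids)
  if (nlevels(lib) < 2L)
    stop("insufficient data: need at least 2 libraries", call. = FALSE)
  if (any(rowSums(table(lib, cond) > 0L) > 1L))
    stop("library_ids must be nested within condition", call. = FALSE)
  per_cond_libs <- table(unique(data.frame(lib, cond))$cond)
  if (any(per_cond_libs < 2L))
    warning("fewer than 2 libraries in a condition: library and condition ",
            "effects are confounded", call. = FALSE)

  dat <- data.frame(.y = lengths, .cond = cond, .lib = lib)
  rhs <- ".cond"
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    stopifnot(nrow(covariates) == length(lengths))
    dat <- cbind(dat, covariates)
    rhs <- paste(c(".cond", names(covariates)), collapse = " + ")
  }
  form <- as.formula(paste(".y ~", rhs, "+ (1 | .lib)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")

  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = dat, REML = reml, control = ctrl))),
    error = function(e) NULL)

  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5))
    return(lmm_ols_fallback(dat, rhs))

  cf <- coef(summary(fit, ddf = if (df_method == "satterthwaite")
    "Satterthwaite" else "lme4"))
  est <- unname(cf[".cond", "Estimate"])
  se <- unname(cf[".cond", "Std. Error"])
  stat <- est / se
  if (df_method == "satterthwaite") {
    df <- unname(cf[".cond", "df"])
    p <- unname(cf[".cond", "Pr(>|t|)"])
    if (!is.finite(p)) return(lmm_ols_fallback(dat, rhs))
  } else {
    df <- NA_real_
    p <- 2 * pnorm(-abs(stat))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(estimate = est, se = se, statistic = stat, df = df, p_value = p,
       variance_components = c(
         lib = vc$vcov[vc$grp == ".lib"][1L],
         resid = vc$vcov[vc$grp == "Residual"][1L]),
       status = "ok")
}

# Degenerate mixed fit: zero library variance reduces the model to OLS.
lmm_ols_fallback <- function(dat, rhs) {
  fit <- lm(as.formula(paste(".y ~", rhs)), data = dat)
  cf <- summary(fit)$coefficients
  se <- unname(cf[".cond", "Std. Error"])
  if (!is.finite(se) || se == 0)
    stop("undefined statistic: zero residual variance", call. = FALSE)
  list(estimate = unname(cf[".cond", "Estimate"]),
       se = se,
       statistic = unname(cf[".cond", "t value"]),
       df = fit$df.residual,
       p_value = unname(cf[".cond", "Pr(>|t|)"]),
       variance_components = c(lib = 0,
                               resid = summary(fit)$sigma^2),
       status = "singular_fallback")
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment (FDR control) by default; plain
#' Bonferroni available. NA entries (failed fits) are passed through
#' unadjusted and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return vector of adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = method)
}

#' Configuration for a differential-length run
#'
#' @param model `"lmm"` (default), `"ttest"` or `"wilcoxon"`.
#' @param logscale logical; log2-transform lengths before fitting, making
#'   the condition estimate a log2 fold change.
#' @param alpha significance level used in summaries (default 0.05).
#' @param min_reads per-condition minimum read count per feature.
#' @param covariates character vector of design-table covariate column
#'   names to include as fixed effects (lmm/ttest only).
#' @param adjust multiple-testing method, `"BH"` or `"bonferroni"`.
#' @param reml,df_method mixed-model fitting options, see [fit_lmm()].
#' @return list of class `"test_config"`.
#' @export
test_config <- function(model = c("lmm", "ttest", "wilcoxon"),
                        logscale = FALSE, alpha = 0.05, min_reads = 5L,
                        covariates = NULL, adjust = c("BH", "bonferroni"),
                        reml = TRUE,
                        df_method = c("satterthwaite", "normal")) {
  model <- match.arg(model)
  adjust <- match.arg(adjust)
  df_method <- match.arg(df_method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (model == "wilcoxon" && length(covariates) > 0L)
    stop("the Wilcoxon model tests the condition variable only and ",
         "cannot adjust for covariates", call. = FALSE)
  structure(list(model = model, logscale = isTRUE(logscale), alpha = alpha,
                 min_reads = as.integer(min_reads), covariates = covariates,
                 adjust = adjust, reml = isTRUE(reml),
                 df_method = df_method),
            class = "test_config")
}

#' Per-feature differential length testing
#'
#' Runs the configured model independently on every feature of a length
#' table: one test of treated-versus-control read length per transcript (or
#' gene), multiple-testing adjustment across all tested features, results
#' sorted by p-value. With `logscale` the lengths are log2-transformed
#' before fitting and the estimate column is a log2 fold change; otherwise
#' it is the length difference in nucleotides. Negative estimates mean
#' shorter RNA in the treated condition. Features whose fit fails are kept
#' in the output with a `status` flag rather than silently dropped.
#'
#' @param tab a `length_table`, normally already passed through
#'   [filter_min_reads()].
#' @param design a `design_table` covering every library in `tab`.
#' @param config a [test_config()].
#' @return data.frame with columns `feature_id`, `n_control`,
#'   `n_condition`, `estimate`, `se`, `statistic`, `p_value`,
#'   `adj_p_value`, `status`, ordered by increasing `p_value`.
#' @export
run_differential_length <- function(tab, design, config = test_config()) {
  tab <- validate_length_table(tab)
  design <- validate_design_table(design)
  stopifnot(inherits(config, "test_config"))
  unknown <- setdiff(unique(tab$library_id), design$library_id)
  if (length(unknown) > 0L)
    stop("library absent from design table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) {
    warning("no features to test", call. = FALSE)
    return(empty_result())
  }

  dmatch <- match(tab$library_id, design$library_id)
  cond <- as.integer(design$condition[dmatch]) - 1L
  y <- if (config$logscale) log2(tab$length) else as.numeric(tab$length)
  covs <- NULL
  if (length(config$covariates) > 0L) {
    missing_covs <- setdiff(config$covariates, names(design))
    if (length(missing_covs) > 0L)
      stop("covariate(s) absent from design table: ",
           paste(missing_covs, collapse = ", "), call. = FALSE)
    covs <- design[dmatch, config$covariates, drop = FALSE]
    rownames(covs) <- NULL
  }

  idx <- split(seq_len(nrow(tab)), tab$feature_id)
  res <- lapply(names(idx), function(fid) {
    i <- idx[[fid]]
    fit <- tryCatch(
      switch(config$model,
        ttest = fit_ttest(y[i], cond[i],
                          covariates = if (is.null(covs)) NULL else
                            covs[i, , drop = FALSE]),
        wilcoxon = fit_wilcoxon(y[i], cond[i]),
        lmm = fit_lmm(y[i], cond[i], tab$library_id[i],
                      covariates = if (is.null(covs)) NULL else
                        covs[i, , drop = FALSE],
                      reml = config$reml, df_method = config$df_method)),
      error = function(e) list(estimate = NA_real_, se = NA_real_,
                               statistic = NA_real_, p_value = NA_real_,
                               status = paste0("failed: ",
                                               conditionMessage(e))))
    data.frame(feature_id = fid,
               n_control = sum(cond[i] == 0L),
               n_condition = sum(cond[i] == 1L),
               estimate = fit$estimate,
               se = if (is.null(fit$se)) NA_real_ else fit$se,
               statistic = fit$statistic,
               p_value = fit$p_value,
               status = fit$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p_value <- adjust_pvalues(out$p_value, method = config$adjust)
  out <- out[order(out$p_value), c("feature_id", "n_control", "n_condition",
                                   "estimate", "se", "statistic", "p_value",
                                   "adj_p_value", "status")]
  rownames(out) <- NULL
  out
}

empty_result <- function() {
  data.frame(feature_id = character(), n_control = integer(),
             n_condition = integer(), estimate = numeric(), se = numeric(),
             statistic = numeric(), p_value = numeric(),
             adj_p_value = numeric(), status = character(),
             stringsAsFactors = FALSE)
}

#' Write differential-length results to TSV
#'
#' @param results data.frame from [run_differential_length()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
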