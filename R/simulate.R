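#' @importFrom stats rnorm setNames
NULL

#' Describe a length-simulation scenario
#'
#' Parameterizes the generative model used to evaluate the differential
#' length tests. Each gene has a true length `true_length`; every library
#' draws a random intercept with standard deviation `lib_sd_frac *
#' true_length` (replicate-level length fluctuation); each read then draws
#' its length from a normal distribution centred on the condition mean —
#' `true_length` for control libraries, `true_length * shortening_prop` for
#' treated — with residual standard deviation `err_sd_frac` times the
#' expected length mean. `shortening_prop = 1` is the null of no change.
#' Lengths are truncated below at 1 nt by resampling (vanishingly rare at
#' the default variance fractions).
#'
#' The defaults are the study conditions used throughout the package's
#' validation: 3 control + 3 treated libraries, library SD 10% of true
#' length, residual SD 20% of the expected mean, 1000 genes per scenario.
#'
#' @param true_length true transcript length in nt (default 1000; because
#'   both variance components scale with it, results are insensitive to the
#'   choice).
#' @param count reads per gene per library (expression proxy).
#' @param shortening_prop treated mean length as a fraction of
#'   `true_length`, in (0, 1].
#' @param n_control_libs,n_condition_libs libraries per condition.
#' @param lib_sd_frac library random-effect SD as a fraction of
#'   `true_length`.
#' @param err_sd_frac residual SD as a fraction of the expected length mean.
#' @param resid_reference `"condition"` (default): the residual SD scales
#'   with the condition-specific mean, so shortened reads are proportionally
#'   less variable; `"grand"`: scales with the true length for both
#'   conditions.
#' @param n_genes independent genes to simulate.
#' @param seed integer seed; each gene gets its own RNG substream, so
#'   per-gene data are reproducible independent of evaluation order.
#' @param draw_count number of residual draws banked per library
#'   (>= `count`); leave at the default unless aligning draws across
#'   read-depth levels, as [run_simulation_study()] does.
#' @return list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(true_length = 1000, count = 50,
                         shortening_prop = 1,
                         n_control_libs = 3, n_condition_libs = 3,
                         lib_sd_frac = 0.10, err_sd_frac = 0.20,
                         resid_reference = c("condition", "grand"),
                         n_genes = 1000, seed = 1,
                         draw_count = count) {
  resid_reference <- match.arg(resid_reference)
  stopifnot(true_length >= 1, count >= 2, shortening_prop > 0,
            shortening_prop <= 1, n_control_libs >= 1,
            n_condition_libs >= 1, lib_sd_frac > 0, err_sd_frac > 0,
            n_genes >= 1, draw_count >= count)
  structure(list(true_length = true_length, count = as.integer(count),
                 shortening_prop = shortening_prop,
                 n_control_libs = as.integer(n_control_libs),
                 n_condition_libs = as.integer(n_condition_libs),
                 lib_sd_frac = lib_sd_frac, err_sd_frac = err_sd_frac,
                 resid_reference = resid_reference,
                 n_genes = as.integer(n_genes), seed = as.integer(seed),
                 draw_count = as.integer(draw_count)),
            class = "sim_scenario")
}

# Evaluate a function once per gene, each gene on its own L'Ecuyer-CMRG
# RNG substream spawned from the scenario seed. Restores the caller's RNG
# state afterwards.
with_gene_streams <- function(seed, n_genes, fun) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    assign(".Random.seed", stream, envir = globalenv())
    out[[g]] <- fun(g)
    stream <- parallel::nextRNGStream(stream)
  }
  out
}

# Draw a gene's standardized variates: one intercept per library plus a
# bank of draw_count residuals per library. Shared across read depths and
# shortening proportions when reusing the same bank.
draw_gene_variates <- function(n_libs, draw_count) {
  list(u = rnorm(n_libs),
       e = matrix(rnorm(n_libs * draw_count), nrow = draw_count))
}

# Materialize read lengths for one gene from standardized draws.
# Returns a numeric matrix of count rows x n_libs columns.
gene_lengths_from_draws <- function(scenario, variates,
                                    count = scenario$count,
                                    shortening_prop =
                                      scenario$shortening_prop) {
  L <- scenario$true_length
  n0 <- scenario$n_control_libs
  n1 <- scenario$n_condition_libs
  cond_of_lib <- rep(c(0L, 1L), c(n0, n1))
  mu <- ifelse(cond_of_lib == 1L, L * shortening_prop, L)
  sd_resid <- if (scenario$resid_reference == "condition")
    scenario$err_sd_frac * mu else rep(scenario$err_sd_frac * L, n0 + n1)
  lib_sd <- scenario$lib_sd_frac * L

  y <- matrix(0, nrow = count, ncol = n0 + n1)
  for (l in seq_len(n0 + n1)) {
    mean_l <- mu[l] + lib_sd * variates$u[l]
    y[, l] <- mean_l + sd_resid[l] * variates$e[seq_len(count), l]
    while (any(y[, l] < 1)) {       # truncate at 1 nt by resampling
      low <- y[, l] < 1
      y[low, l] <- mean_l + sd_resid[l] * rnorm(sum(low))
    }
  }
  y
}

#' Simulate one gene's read lengths
#'
#' Draws read lengths for a single gene under the mixed model of
#' [sim_scenario()]: a normal random intercept per library plus normal
#' residual noise around the condition mean. Requires a seeded RNG (the
#' caller controls reproducibility).
#'
#' @param scenario a [sim_scenario()].
#' @return data.frame with columns `length` (numeric, nt), `library_id`,
#'   `condition` (0 control / 1 treated), `count` reads per library.
#' @export
simulate_gene <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n0 <- scenario$n_control_libs
  n1 <- scenario$n_condition_libs
  variates <- draw_gene_variates(n0 + n1, scenario$draw_count)
  y <- gene_lengths_from_draws(scenario, variates)
  lib_names <- c(paste0("ctrl_", seq_len(n0)), paste0("trt_", seq_len(n1)))
  data.frame(
    length = as.vector(y),
    library_id = rep(lib_names, each = scenario$count),
    condition = rep(rep(c(0L, 1L), c(n0, n1)), each = scenario$count),
    stringsAsFactors = FALSE)
}

#' Simulate a full scenario as a length table and design table
#'
#' Generates `n_genes` independent genes, each on its own RNG substream of
#' the scenario seed, and emits them in the package's canonical formats so
#' the statistical module consumes them unchanged. Simulated lengths are
#' rounded to whole nucleotides and laid out as reads spanning
#' `[0, length)`.
#'
#' @param scenario a [sim_scenario()].
#' @return list with elements `table` (a `length_table`) and `design`
#'   (a `design_table` with control as reference level).
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  genes <- with_gene_streams(scenario$seed, scenario$n_genes,
                             function(g) simulate_gene(scenario))
  gene_ids <- sprintf("gene_%04d", seq_len(scenario$n_genes))
  n_per_gene <- nrow(genes[[1L]])
  all <- do.call(rbind, genes)
  feature_id <- rep(gene_ids, each = n_per_gene)
  len <- pmax(1L, as.integer(round(all$length)))
  tab <- length_table(
    read_id = paste0(feature_id, ":", all$library_id, ":",
                     sequence(rep(n_per_gene, scenario$n_genes))),
    library_id = all$library_id,
    feature_id = feature_id,
    five_p = 0L, three_p = len,
    provenance = sprintf(
      "simulated: L=%g prop=%g count=%d genes=%d seed=%d",
      scenario$true_length, scenario$shortening_prop, scenario$count,
      scenario$n_genes, scenario$seed))
  design <- design_table(
    library_id = c(paste0("ctrl_", seq_len(scenario$n_control_libs)),
                   paste0("trt_", seq_len(scenario$n_condition_libs))),
    condition = rep(c("control", "treated"),
                    c(scenario$n_control_libs, scenario$n_condition_libs)),
    reference = "control")
  list(table = tab, design = design)
}

#' Run a simulation study over a grid of read depths and shortening levels
#'
#' For every (count, proportion) cell: simulate the scenario, run
#' [run_differential_length()], and record the per-gene estimates and
#' p-values together with the cell summary (mean estimate, bias, fraction
#' significant at `config$alpha`). Genes are simulated on per-gene RNG
#' substreams of `seed`, and the same standardized draws are reused across
#' all cells (common random numbers): a gene keeps its library effects and
#' its residual stream as the read depth or shortening proportion changes,
#' so comparisons across cells are not confounded by independent sampling
#' noise.
#'
#' @param counts integer vector of reads per gene per library.
#' @param props numeric vector of shortening proportions in (0, 1].
#' @param config a [test_config()]; all cells use the same model.
#' @param true_length,n_genes,lib_sd_frac,err_sd_frac,n_control_libs,n_condition_libs,resid_reference
#'   scenario parameters, see [sim_scenario()].
#' @param seed master seed for the study.
#' @return list of class `"sim_study"`: one element per cell, each with
#'   `scenario`, `per_gene` (data.frame: feature_id, true_value, estimate,
#'   p_value, status) and `summary` (one-row data.frame). Cells where a
#'   gene's fit fails carry the flagged row; the grid never aborts.
#' @export
run_simulation_study <- function(counts = c(10, 50, 100, 200),
                                 props = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
                                 config = test_config("lmm"),
                                 true_length = 1000, n_genes = 1000,
                                 lib_sd_frac = 0.10, err_sd_frac = 0.20,
                                 n_control_libs = 3, n_condition_libs = 3,
                                 resid_reference = "condition",
                                 seed = 1) {
  stopifnot(length(counts) >= 1, length(props) >= 1)
  counts <- sort(as.integer(counts))
  max_count <- max(counts)
  cells <- expand.grid(count = counts, prop = props)
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    scen <- sim_scenario(true_length = true_length,
                         count = cells$count[k],
                         shortening_prop = cells$prop[k],
                         n_control_libs = n_control_libs,
                         n_condition_libs = n_condition_libs,
                         lib_sd_frac = lib_sd_frac,
                         err_sd_frac = err_sd_frac,
                         resid_reference = resid_reference,
                         n_genes = n_genes, seed = seed,
                         draw_count = max_count)
    sim <- simulate_scenario(scen)
    res <- suppressMessages(
      run_differential_length(sim$table, sim$design, config))
    true_value <- if (config$logscale) log2(scen$shortening_prop) else
      scen$true_length * (scen$shortening_prop - 1)
    per_gene <- data.frame(feature_id = res$feature_id,
                           true_value = true_value,
                           estimate = res$estimate,
                           p_value = res$p_value,
                           status = res$status,
                           stringsAsFactors = FALSE)
    ok <- !is.na(per_gene$p_value)
    summary_row <- data.frame(
      count = scen$count, proportion = scen$shortening_prop,
      model = config$model, logscale = config$logscale,
      n_genes = scen$n_genes, n_failed = sum(!ok),
      true_value = true_value,
      mean_estimate = mean(per_gene$estimate[ok]),
      bias = mean(per_gene$estimate[ok]) - true_value,
      mean_abs_error = mean(abs(per_gene$estimate[ok] - true_value)),
      frac_significant = mean(per_gene$p_value[ok] < config$alpha),
      metric = if (scen$shortening_prop == 1) "fpr" else "power",
      stringsAsFactors = FALSE)
    out[[k]] <- list(scenario = scen, per_gene = per_gene,
                     summary = summary_row)
  }
  structure(out, class = "sim_study", seed = seed, alpha = config$alpha)
}

#' Summarize a simulation study
#'
#' Collapses a [run_simulation_study()] result into one long-format row per
#' grid cell: mean estimate, bias against the generator truth, mean
#' absolute error, and the fraction of genes significant at the study alpha
#' (labelled `fpr` for null cells, `power` otherwise).
#'
#' @param study a `sim_study`.
#' @param path optional TSV output path.
#' @return data.frame with columns `count`, `proportion`, `model`,
#'   `logscale`, `n_genes`, `n_failed`, `true_value`, `mean_estimate`,
#'   `bias`, `mean_abs_error`, `frac_significant`, `metric`.
#' @export
summarize_simulation <- function(study, path = NULL) {
  stopifnot(inherits(study, "sim_study"), length(study) >= 1)
  out <- do.call(rbind, lapply(study, `[[`, "summary"))
  out <- out[order(out$proportion, out$count), ]
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
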