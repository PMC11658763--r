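#' Construct an experimental design table
#'
#' Maps each sequencing library (replicate) to a condition, with the control
#' condition declared explicitly as the reference level — never inferred
#' from string sort order. The condition coefficient of every model then
#' measures treated minus control, so a negative length estimate means
#' shorter RNA in the treated condition.
#'
#' @param library_id character vector of library identifiers (unique).
#' @param condition character/factor vector with exactly two levels.
#' @param reference the condition level to treat as control (coded 0).
#'   Defaults to the first value of `condition`.
#' @param covariates optional data.frame of extra per-library covariates
#'   (numeric or factor), one row per library, to be carried into t-test or
#'   mixed-model fits.
#' @return A `data.frame` of class `"design_table"` with columns
#'   `library_id`, `condition` (factor, reference level first) and any
#'   covariates.
#' @export
design_table <- function(library_id, condition, reference = NULL,
                         covariates = NULL) {
  library_id <- as.character(library_id)
  condition <- as.character(condition)
  if (is.null(reference)) reference <- condition[1L]
  d <- data.frame(library_id = library_id,
                  condition = condition,
                  stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(d))
    d <- cbind(d, covariates)
  }
  d$condition <- stats::relevel(factor(d$condition), ref = reference)
  class(d) <- c("design_table", "data.frame")
  d <- validate_design_table(d)
  per_level <- table(d$condition)
  if (any(per_level < 2L))
    warning("fewer than 2 libraries in condition '",
            names(per_level)[per_level < 2L][1L],
            "': library and condition effects are confounded for the ",
            "mixed model", call. = FALSE)
  d
}

#' Validate a design table
#'
#' @param design a data.frame with `library_id` and a two-level factor
#'   `condition`.
#' @return `design`, classed as a `design_table`.
#' @export
validate_design_table <- function(design) {
  if (!all(c("library_id", "condition") %in% names(design)))
    stop("design table needs columns library_id and condition",
         call. = FALSE)
  if (!is.factor(design$condition))
    design$condition <- factor(design$condition)
  if (nlevels(design$condition) != 2L)
    stop("condition must have exactly 2 levels, got ",
         nlevels(design$condition), call. = FALSE)
  if (anyDuplicated(design$library_id))
    stop("duplicate library_id in design table", call. = FALSE)
  per_level <- table(design$condition)
  if (any(per_level < 1L))
    stop("each condition needs at least one library", call. = FALSE)
  class(design) <- unique(c("design_table", class(design)))
  design
}

#' Read a design table from TSV
#'
#' @param path TSV with header columns `library_id`, `condition` and any
#'   extra covariate columns.
#' @param reference condition level to use as control; defaults to the
#'   condition of the first row.
#' @return A `design_table`.
#' @export
load_design_table <- function(path, reference = NULL) {
  if (!file.exists(path))
    stop("design table file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("library_id", "condition") %in% names(raw)))
    stop("design TSV '", path,
         "' needs columns library_id and condition", call. = FALSE)
  covs <- raw[, setdiff(names(raw), c("library_id", "condition")),
              drop = FALSE]
  design_table(raw$library_id, raw$condition, reference = reference,
               covariates = if (ncol(covs) > 0L) covs else NULL)
}

#' Write a design table to TSV
#'
#' @param design a `design_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  design <- validate_design_table(design)
  out <- as.data.frame(design)
  out$condition <- as.character(out$condition)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
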