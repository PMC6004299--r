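#' Read and write expression matrices and clinical tables
#'
#' The interchange format is tab-separated text, matching the conventions of
#' GEO series matrices and TCGA tab dumps: the expression file has gene
#' identifiers in the first column and one column per sample; the clinical
#' file has one row per sample with `sample_id` first.  Gzipped files are
#' read transparently.
#'
#' @param path File path.
#' @return `read_expression()` returns a numeric genes x samples matrix with
#'   gene rownames and sample colnames; `read_clinical()` returns a tibble.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_expression <- function(path) {
  # base read.delim: correctly rounded float parsing, so write/read
  # round-trips values to the exact double
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("expression file needs a gene column plus sample columns.")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicated gene identifier(s) in %s: %s",
                  path, paste(unique(genes[duplicated(genes)])[1:3], collapse = ", ")))
  }
  if (anyDuplicated(names(df)[-1])) {
    abort(sprintf("duplicated sample column(s): %s",
                  paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", ")))
  }
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(vals)[which(bad)[1]]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))))[1]
    abort(sprintf("non-numeric expression value at gene row %s, sample column '%s'.",
                  ifelse(is.na(row), "?", row), col))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' @rdname pipeline_io
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  check_clinical(df)
  as_tibble(df)
}

#' @rdname pipeline_io
#' @param expr Genes x samples matrix.
#' @param gene_col Header for the gene-identifier column.
#' @export
write_expression <- function(expr, path, gene_col = "gene_id") {
  check_expression(expr)
  df <- tibble::as_tibble(expr)
  df <- dplyr::bind_cols(tibble(!!gene_col := rownames(expr)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  check_clinical(clinical)
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `expression.tsv` (gene x sample), `clinical.tsv` (sample per row)
#' and `truth.tsv` (planted genes) under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(cohort$expression, paths["expression"])
  write_clinical(cohort$clinical, paths["clinical"])
  readr::write_tsv(cohort$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}

# Reconcile expression and clinical sample sets; returns matched pair and
# reports drops.
reconcile_samples <- function(expr, clinical, quiet = FALSE) {
  shared <- intersect(colnames(expr), clinical$sample_id)
  dropped_expr <- setdiff(colnames(expr), shared)
  dropped_clin <- setdiff(clinical$sample_id, shared)
  if (length(dropped_expr) && !quiet) {
    warn(sprintf("%d expression sample(s) absent from clinical table, excluded: %s%s",
                 length(dropped_expr), paste(head(dropped_expr, 3), collapse = ", "),
                 if (length(dropped_expr) > 3) ", ..." else ""))
  }
  if (length(dropped_clin) && !quiet) {
    warn(sprintf("%d clinical sample(s) absent from expression matrix, excluded.",
                 length(dropped_clin)))
  }
  list(expr = expr[, shared, drop = FALSE],
       clinical = clinical[match(shared, clinical$sample_id), , drop = FALSE],
       dropped = c(dropped_expr, dropped_clin))
}
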