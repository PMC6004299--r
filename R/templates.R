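#' Build good/poor prognosis expression templates
#'
#' The templates are the per-gene arithmetic means of the good-prognosis and
#' poor-prognosis training samples, restricted to the signature's gene set.
#'
#' @param expr Genes x samples expression matrix (typically z-scored per
#'   gene; see [loocv_sweep()]).
#' @param labels Tibble with `sample_id` and `label` (poor/good).
#' @param genes Gene subset defining the signature (non-empty, present in
#'   `expr`).
#' @return A `prognosis_templates` tibble: `gene`, `good_mean`, `poor_mean`.
#' @export
build_templates <- function(expr, labels, genes) {
  check_expression(expr)
  if (!length(genes)) abort("`genes` must be non-empty.")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    abort(sprintf("gene(s) absent from expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  lab <- labels |> filter(.data$label %in% c("poor", "good"))
  good <- lab$sample_id[lab$label == "good"]
  poor <- lab$sample_id[lab$label == "poor"]
  if (!length(good) || !length(poor)) abort("both prognosis classes must be non-empty.")
  x <- expr[genes, , drop = FALSE]
  out <- tibble(gene = genes,
                good_mean = unname(rowMeans(x[, good, drop = FALSE])),
                poor_mean = unname(rowMeans(x[, poor, drop = FALSE])))
  class(out) <- c("prognosis_templates", class(out))
  out
}

# correlation of each column of x (genes x samples) with vector t;
# zero-variance columns or template -> 0
cor_to_template <- function(x, t) {
  r <- suppressWarnings(as.vector(cor(x, t)))
  r[is.na(r)] <- 0
  r
}

#' Risk coefficient of samples against prognosis templates
#'
#' For each sample, risk-coef = Pearson r(profile, good template) - Pearson
#' r(profile, poor template), restricted to the template's gene set.  Values
#' lie in \[-2, 2\]; low values indicate poor-prognosis-like profiles.
#' Zero-variance profiles get both correlations (hence the risk-coef) set
#' to 0.
#'
#' @param expr Genes x samples expression matrix containing the template
#'   genes.
#' @param templates A [build_templates()] result.
#' @return Tibble `sample_id`, `r_good`, `r_poor`, `risk_coef`.
#' @export
risk_coef <- function(expr, templates) {
  check_expression(expr)
  stopifnot(inherits(templates, "prognosis_templates"))
  if (nrow(templates) < 2L) abort("risk-coef needs at least 2 signature genes.")
  missing <- setdiff(templates$gene, rownames(expr))
  if (length(missing)) {
    abort(sprintf("profile/template gene mismatch; missing: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  x <- expr[templates$gene, , drop = FALSE]
  r_good <- cor_to_template(x, templates$good_mean)
  r_poor <- cor_to_template(x, templates$poor_mean)
  tibble(sample_id = colnames(expr), r_good = r_good, r_poor = r_poor,
         risk_coef = r_good - r_poor)
}

#' Classify samples by rank cut on risk coefficients
#'
#' Orders samples by risk coefficient from smallest to largest (ties broken
#' by sample identifier) and labels the first `n_high` as high genomic risk,
#' the rest low.
#'
#' @param risk Tibble with `sample_id` and `risk_coef` (from [risk_coef()]).
#' @param n_high Number of samples to call high risk (0..n).
#' @return The input with a `genomic_risk` factor column (high/low).
#' @export
rank_cut_classify <- function(risk, n_high) {
  stopifnot(all(c("sample_id", "risk_coef") %in% names(risk)))
  n <- nrow(risk)
  if (n_high < 0 || n_high > n) abort("`n_high` must be between 0 and the number of samples.")
  ord <- order(risk$risk_coef, risk$sample_id)
  genomic <- rep("low", n)
  genomic[ord[seq_len(n_high)]] <- "high"
  risk |> mutate(genomic_risk = factor(genomic, levels = c("high", "low")))
}
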