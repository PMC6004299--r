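# Pearson correlation of every nested prefix of genes (rows of x, in order)
# with the matching prefix of template t, for every sample (column) at once.
# Returns an m x n matrix whose row s is the correlation over the top-s genes.
# Prefixes with zero variance on either side give 0.
prefix_cor <- function(x, t) {
  m <- nrow(x)
  s <- seq_len(m)
  sx <- apply(x, 2L, cumsum)
  sxx <- apply(x * x, 2L, cumsum)
  sxt <- apply(x * t, 2L, cumsum)
  st <- cumsum(t)
  stt <- cumsum(t * t)
  cov <- sxt - sx * (st / s)
  varx <- sxx - sx^2 / s
  vart <- stt - st^2 / s
  denom <- sqrt(pmax(varx, 0) * pmax(vart, 0))
  r <- ifelse(denom > 1e-12, cov / denom, 0)
  matrix(r, nrow = m, dimnames = dimnames(x))
}

#' Candidate signature sizes for the nested sweep
#'
#' The default LOOCV grid starts at the top `step` genes of the ranking and
#' grows by `step` until the list is exhausted, so 1510 ranked genes with
#' the default step of 2 yield 755 candidate signatures.
#'
#' @param n_ranked Number of ranked genes available.
#' @param step Grid increment (default 2).
#' @return Integer vector of signature sizes.
#' @export
candidate_sizes <- function(n_ranked, step = 2L) {
  if (n_ranked < step) return(integer(0))
  seq.int(step, n_ranked, by = step)
}

#' Leave-one-out cross-validation over nested signature sizes
#'
#' Evaluates every nested prefix signature of a ranked gene list by
#' leave-one-out cross-validation.  For each left-out sample the class
#' templates are rebuilt from the remaining samples, risk coefficients are
#' computed for all samples (including the left-out one), the cohort is
#' ranked by risk coefficient and the `n_high` smallest are called high
#' genomic risk; an error is counted when the left-out sample's genomic risk
#' disagrees with its real risk (poor = high, good = low).  By default
#' candidate sizes step by two from the top of the list, so a 1510-gene
#' ranking yields 755 candidate signatures.
#'
#' @param expr Genes x samples expression matrix.
#' @param labels Tibble with `sample_id`, `label` (poor/good); excluded
#'   samples are ignored.
#' @param ranked_genes Character vector of genes ordered by decreasing
#'   screening |r| (e.g. `screen_genes(...)$gene`).
#' @param sizes Signature sizes to evaluate; default `seq(2, length(ranked_genes), by = 2)`.
#'   Sizes beyond the ranking are dropped with a warning.
#' @param n_high Number of samples called high risk at the rank cut;
#'   default = number of poor-prognosis samples.
#' @param scale Z-score each gene across the analysis samples first
#'   (default TRUE).
#' @return A `loocv_report`: tibble `size`, `errors`, plus a `predictions`
#'   list-column (per left-out sample: predicted vs real risk).  The sizes
#'   achieving the minimum error count are in `attr(, "best_sizes")`.
#' @export
loocv_sweep <- function(expr, labels, ranked_genes, sizes = NULL,
                        n_high = NULL, scale = TRUE) {
  check_expression(expr)
  lab <- labels |>
    filter(.data$label %in% c("poor", "good")) |>
    arrange(.data$sample_id)
  ids <- lab$sample_id
  n <- length(ids)
  if (n < 3L) abort("need at least 3 labelled samples for LOOCV.")
  ranked_genes <- as.character(ranked_genes)
  if (is.null(sizes)) sizes <- candidate_sizes(length(ranked_genes))
  if (any(sizes > length(ranked_genes))) {
    warn(sprintf("%d size(s) exceed the %d ranked genes; truncated.",
                 sum(sizes > length(ranked_genes)), length(ranked_genes)))
    sizes <- sizes[sizes <= length(ranked_genes)]
  }
  if (!length(sizes)) abort("no usable signature sizes.")
  sizes <- sort(unique(as.integer(sizes)))
  is_poor <- lab$label == "poor"
  n_high <- n_high %||% sum(is_poor)

  x <- expr[ranked_genes, ids, drop = FALSE]
  if (scale) x <- scale_rows(x)
  sum_poor <- rowSums(x[, is_poor, drop = FALSE])
  sum_good <- rowSums(x[, !is_poor, drop = FALSE])
  n_poor <- sum(is_poor)
  n_good <- n - n_poor

  pred <- matrix(NA_character_, nrow = length(sizes), ncol = n,
                 dimnames = list(NULL, ids))
  for (i in seq_len(n)) {
    xi <- x[, i]
    if (is_poor[i]) {
      tp <- (sum_poor - xi) / (n_poor - 1L)
      tg <- sum_good / n_good
    } else {
      tp <- sum_poor / n_poor
      tg <- (sum_good - xi) / (n_good - 1L)
    }
    risk <- prefix_cor(x, tg) - prefix_cor(x, tp)
    risk <- risk[sizes, , drop = FALSE]
    # position of the left-out sample in the small-to-large ranking,
    # ties broken by sample identifier
    ri <- risk[, i]
    less <- rowSums(risk < ri)
    tie_before <- rowSums((risk == ri) & rep(ids < ids[i], each = length(sizes)))
    pred[, i] <- ifelse(less + tie_before + 1L <= n_high, "high", "low")
  }

  real <- ifelse(is_poor, "high", "low")
  err_mat <- pred != rep(real, each = length(sizes))
  errors <- rowSums(err_mat)
  predictions <- purrr::map(seq_along(sizes), function(k) {
    tibble(sample_id = ids, real_risk = real, genomic_risk = pred[k, ],
           error = unname(err_mat[k, ]))
  })
  out <- tibble(size = sizes, errors = as.integer(errors),
                predictions = predictions)
  class(out) <- c("loocv_report", class(out))
  attr(out, "best_sizes") <- sizes[errors == min(errors)]
  attr(out, "n_high") <- n_high
  out
}

#' @export
print.loocv_report <- function(x, ...) {
  best <- attr(x, "best_sizes")
  cat(sprintf("<loocv_report> %d signature sizes; min error count %d at size(s): %s\n",
              nrow(x), min(x$errors), paste(best, collapse = ", ")))
  invisible(x)
}

#' Leave-one-out cross-validation without information leak
#'
#' A stricter LOOCV in which the correlation screen itself is recomputed
#' inside every fold: the left-out sample never influences gene selection.
#' Each fold screens genes on the remaining samples at `r_threshold`,
#' builds templates on the fold's own gene list, computes risk coefficients
#' for all samples, applies the rank cut, and records the left-out sample's
#' predicted vs real risk.  Folds whose screen retains fewer than 2 genes
#' fall back to the full gene list (flagged).
#'
#' @inheritParams loocv_sweep
#' @param r_threshold Screening cutoff applied within each fold.
#' @param coding Label coding passed to [gene_prognosis_correlation()].
#' @return A `loocv_noleak` tibble: one row per fold with `sample_id`,
#'   `n_genes`, `genes` (list-column), `overlap` (fraction of the full-data
#'   screen list recovered in the fold), `genomic_risk`, `real_risk`,
#'   `error`, `fallback`.  The full-data screened gene list is in
#'   `attr(, "full_screen")`.
#' @export
loocv_no_leak <- function(expr, labels, r_threshold = 0.3, n_high = NULL,
                          scale = TRUE, coding = c(poor = 1, good = 0)) {
  check_expression(expr)
  lab <- labels |>
    filter(.data$label %in% c("poor", "good")) |>
    arrange(.data$sample_id)
  ids <- lab$sample_id
  n <- length(ids)
  is_poor <- lab$label == "poor"
  n_high <- n_high %||% sum(is_poor)
  x <- expr[, ids, drop = FALSE]
  if (scale) x <- scale_rows(x)

  full_screen <- screen_genes(
    gene_prognosis_correlation(x, lab, coding = coding), r_threshold)$gene

  folds <- purrr::map(seq_len(n), function(i) {
    lab_i <- lab[-i, , drop = FALSE]
    if (min(table(factor(lab_i$label, levels = c("poor", "good")))) < 2L) {
      abort("a fold leaves fewer than 2 samples in a prognosis class.")
    }
    cors <- gene_prognosis_correlation(x[, -i, drop = FALSE], lab_i, coding = coding)
    sig <- screen_genes(cors, r_threshold)$gene
    fallback <- length(sig) < 2L
    if (fallback) sig <- rownames(x)
    templates <- build_templates(x[, -i, drop = FALSE], lab_i, sig)
    risk <- risk_coef(x, templates)
    cls <- rank_cut_classify(risk, n_high)
    tibble(sample_id = ids[i],
           n_genes = length(sig),
           genes = list(sig),
           overlap = if (length(full_screen)) {
             length(intersect(sig, full_screen)) / length(full_screen)
           } else NA_real_,
           genomic_risk = as.character(cls$genomic_risk[cls$sample_id == ids[i]]),
           fallback = fallback)
  })
  out <- bind_rows(folds) |>
    mutate(real_risk = ifelse(is_poor, "high", "low"),
           error = .data$genomic_risk != .data$real_risk)
  class(out) <- c("loocv_noleak", class(out))
  attr(out, "full_screen") <- full_screen
  out
}
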