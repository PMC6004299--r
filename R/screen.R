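#' Correlate each gene's expression with prognosis category
#'
#' Computes the Pearson correlation (point-biserial, since the phenotype is
#' binary) between every gene's expression and the numeric coding of the
#' poor/good prognosis label.  With the default coding poor = 1, good = 0 a
#' positive correlation means higher expression in poor-prognosis patients;
#' any affine recoding changes at most the sign.  Genes with zero variance
#' across the labelled samples get r = 0 by convention, flagged in the
#' output.
#'
#' @param expr Genes x samples expression matrix.
#' @param labels Output of [assign_prognosis_labels()] (or any tibble with
#'   `sample_id` and `label` in poor/good); excluded samples are dropped.
#' @param coding Named numeric vector mapping `poor` and `good` to numbers.
#' @param log2 Correlate `log2(expr + 1)` instead of the values as provided
#'   (default FALSE).
#' @return Tibble `gene`, `r`, `zero_variance`, one row per gene.
#' @export
gene_prognosis_correlation <- function(expr, labels,
                                       coding = c(poor = 1, good = 0),
                                       log2 = FALSE) {
  check_expression(expr)
  stopifnot(all(c("poor", "good") %in% names(coding)))
  lab <- labels |> filter(.data$label %in% c("poor", "good"))
  missing <- setdiff(lab$sample_id, colnames(expr))
  if (length(missing)) {
    abort(sprintf("labelled sample(s) absent from expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (min(table(droplevels(factor(lab$label)))) < 2L) {
    abort("each prognosis class needs at least 2 samples for a correlation.")
  }
  x <- expr[, lab$sample_id, drop = FALSE]
  if (log2) x <- log2(x + 1)
  y <- unname(coding[as.character(lab$label)])
  r <- as.vector(suppressWarnings(cor(t(x), y)))
  zero_var <- is.na(r)
  r[zero_var] <- 0
  tibble(gene = rownames(expr), r = r, zero_variance = zero_var)
}

#' Filter and rank genes by correlation magnitude
#'
#' Retains genes whose absolute correlation is at least `r_threshold` and
#' orders them by |r| descending, ties broken by gene identifier.
#'
#' @param correlations Tibble from [gene_prognosis_correlation()].
#' @param r_threshold Magnitude cutoff in (0, 1\]; default 0.3.  The
#'   comparison is inclusive (|r| >= threshold).
#' @return Tibble `gene`, `r`, `abs_r` of the retained genes, ranked; the
#'   retained count is `attr(, "n_retained")`.
#' @export
screen_genes <- function(correlations, r_threshold = 0.3) {
  stopifnot(all(c("gene", "r") %in% names(correlations)))
  if (r_threshold < 0 || r_threshold > 1) abort("`r_threshold` must be in [0, 1].")
  out <- correlations |>
    mutate(abs_r = abs(.data$r)) |>
    filter(.data$abs_r >= r_threshold) |>
    arrange(desc(.data$abs_r), .data$gene) |>
    select("gene", "r", "abs_r")
  attr(out, "n_retained") <- nrow(out)
  attr(out, "r_threshold") <- r_threshold
  out
}

#' Monte-Carlo permutation null for the retained-gene count
#'
#' Estimates how many genes would pass the correlation screen by chance:
#' prognosis labels are permuted across samples `n_permutations` times, the
#' per-gene correlations recomputed, and the count of genes with
#' |r| >= `r_threshold` recorded per trial.  The empirical p-value for the
#' observed count uses the add-one permutation estimator
#' p = (# trials with count >= observed + 1) / (n_permutations + 1),
#' which cannot return 0.
#'
#' @inheritParams gene_prognosis_correlation
#' @param log2 Screen on `log2(expr + 1)` (default FALSE).
#' @param r_threshold Magnitude cutoff (default 0.3).
#' @param n_permutations Number of Monte-Carlo trials (>= 1).
#' @param seed Integer seed; identical seeds reproduce identical null counts.
#' @return A `perm_null` object: list with `observed` (retained-gene count on
#'   the real labels), `null_counts` (integer vector, one per trial),
#'   `p_value`, `r_threshold`, `n_permutations`.
#' @export
permutation_null <- function(expr, labels, r_threshold = 0.3,
                             n_permutations = 10000, seed = 1L,
                             coding = c(poor = 1, good = 0), log2 = FALSE) {
  if (!is_count(n_permutations)) {
    abort("`n_permutations` must be a positive integer.")
  }
  lab <- labels |> filter(.data$label %in% c("poor", "good"))
  x_t <- t(expr[, lab$sample_id, drop = FALSE])
  if (log2) x_t <- log2(x_t + 1)
  y <- unname(coding[as.character(lab$label)])
  obs_r <- as.vector(suppressWarnings(cor(x_t, y)))
  observed <- sum(abs(obs_r) >= r_threshold, na.rm = TRUE)

  set.seed(seed)
  counts <- integer(n_permutations)
  chunk <- 500L
  done <- 0L
  while (done < n_permutations) {
    b <- min(chunk, n_permutations - done)
    perms <- vapply(seq_len(b), function(i) sample(y), numeric(length(y)))
    r <- suppressWarnings(cor(x_t, perms))
    counts[done + seq_len(b)] <- colSums(abs(r) >= r_threshold, na.rm = TRUE)
    done <- done + b
  }
  structure(
    list(observed = observed,
         null_counts = counts,
         p_value = (sum(counts >= observed) + 1) / (n_permutations + 1),
         r_threshold = r_threshold,
         n_permutations = n_permutations,
         seed = seed),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> observed %d genes at |r| >= %.2f; empirical p = %.4g (%d trials)\n",
              x$observed, x$r_threshold, x$p_value, x$n_permutations))
  invisible(x)
}
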