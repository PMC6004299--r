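#' ROC analysis of risk coefficients against real risk
#'
#' Builds receiver operating characteristic curves by sweeping a threshold
#' over the negated risk coefficient (low risk-coef means a
#' poor-prognosis-like profile, so it is the "positive" direction).  The
#' area under the curve is computed by the trapezoid rule and its standard
#' error by the Hanley-McNeil formula; a normal-approximation 95% confidence
#' interval is attached.
#'
#' @param scores A named list of per-signature scores.  Each element is
#'   either a tibble with `sample_id` and `risk_coef` (as from
#'   [risk_coef()]) or a named numeric vector of risk coefficients.
#' @param labels Tibble with `sample_id` and `label` (poor/good); poor is
#'   the positive class.
#' @return A `roc_comparison` tibble: one row per signature with `signature`,
#'   `auc`, `se`, `ci_lower`, `ci_upper`, `n_pos`, `n_neg` and a `curve`
#'   list-column of (`fpr`, `tpr`) points from (0,0) to (1,1).
#' @examples
#' labs <- tibble::tibble(sample_id = letters[1:4],
#'                        label = c("poor", "poor", "good", "good"))
#' sc <- list(toy = stats::setNames(c(0.1, 0.2, 0.3, 0.4), letters[1:4]))
#' roc_compare(sc, labs)$auc  # perfect separation
#' @export
roc_compare <- function(scores, labels) {
  if (!is.list(scores) || is.data.frame(scores)) scores <- list(signature = scores)
  if (is.null(names(scores))) names(scores) <- paste0("sig", seq_along(scores))
  rows <- purrr::imap(scores, function(sc, nm) {
    if (is.data.frame(sc)) sc <- setNames(sc$risk_coef, sc$sample_id)
    lab <- labels |> filter(.data$label %in% c("poor", "good"),
                            .data$sample_id %in% names(sc))
    y <- lab$label == "poor"
    if (!any(y) || all(y)) abort("ROC needs at least one poor and one good sample.")
    x <- -unname(sc[lab$sample_id])  # larger = more poor-like
    curve <- roc_points(x, y)
    auc <- trapezoid_auc(curve$fpr, curve$tpr)
    se <- hanley_mcneil_se(auc, sum(y), sum(!y))
    tibble(signature = nm, auc = auc, se = se,
           ci_lower = max(0, auc - qnorm(0.975) * se),
           ci_upper = min(1, auc + qnorm(0.975) * se),
           n_pos = sum(y), n_neg = sum(!y), curve = list(curve))
  })
  out <- bind_rows(rows)
  class(out) <- c("roc_comparison", class(out))
  out
}

# ROC points for predictor x (larger = positive call) and logical truth y.
roc_points <- function(x, y) {
  ord <- order(x, decreasing = TRUE)
  x <- x[ord]
  y <- y[ord]
  # group tied predictor values so the curve moves diagonally through ties
  last_of_tie <- c(x[-1] != x[-length(x)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(!y)[last_of_tie]
  tibble(fpr = c(0, fp / sum(!y)), tpr = c(0, tp / sum(y)))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}
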