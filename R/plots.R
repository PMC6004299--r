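#' Plot LOOCV error counts across signature sizes
#'
#' @param object A `loocv_report`.
#' @param ... Unused.
#' @return A ggplot: error count vs signature size, minimisers highlighted.
#' @export
autoplot.loocv_report <- function(object, ...) {
  d <- tidy(object)
  best <- attr(object, "best_sizes")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$errors)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = d |> filter(.data$size %in% best),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "signature size (genes)", y = "LOOCV error count",
                  title = "Cross-validated errors across nested signatures") +
    ggplot2::theme_minimal()
}

#' Plot ROC curves for a set of candidate signatures
#'
#' @param object A `roc_comparison` from [roc_compare()].
#' @param ... Unused.
#' @return A ggplot of the ROC curves with AUCs in the legend.
#' @export
autoplot.roc_comparison <- function(object, ...) {
  d <- object |>
    mutate(label = sprintf("%s (AUC %.3f)", .data$signature, .data$auc)) |>
    select("label", "curve") |>
    tidyr::unnest("curve")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                  colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves of a survival comparison
#'
#' @param object A `survival_comparison` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot of the product-limit curves, annotated with the
#'   log-rank p-value.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  d <- tidy(object) |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, survival = 1), .x)) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (years)", y = "survival probability",
                  colour = "risk group",
                  title = sprintf("%s: log-rank p = %.3g",
                                  toupper(object$endpoint), object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null of the gene screen
#'
#' @param object A `perm_null` from [permutation_null()].
#' @param ... Unused.
#' @return A ggplot histogram of null retained-gene counts with the
#'   observed count marked.
#' @export
autoplot.perm_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$n_passing)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = sprintf("genes with |r| >= %.2f per trial", object$r_threshold),
                  y = "trials",
                  title = sprintf("Permutation null (empirical p = %.4g)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
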