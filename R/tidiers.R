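#' Tidy a weighted signature
#'
#' @param x A `weighted_signature`.
#' @param ... Unused.
#' @return Tibble `gene`, `beta` in signature order.
#' @export
tidy.weighted_signature <- function(x, ...) x$genes

#' @rdname tidy.weighted_signature
#' @return For `glance()`: one-row tibble with the selected size, the
#'   test-set KM log-rank p-value, the endpoint, and arm sizes.
#' @export
glance.weighted_signature <- function(x, ...) {
  tibble(k_selected = x$k_selected, km_p = x$km_p, endpoint = x$endpoint,
         n_train = x$n_train, n_test = x$n_test)
}

#' Tidy a survival comparison
#'
#' @param x A `survival_comparison` from [km_logrank()].
#' @param ... Unused.
#' @return The Kaplan-Meier curve points (`group`, `time`, `survival`,
#'   `n_risk`, `n_event`).
#' @export
tidy.survival_comparison <- function(x, ...) x$curves

#' @rdname tidy.survival_comparison
#' @export
glance.survival_comparison <- function(x, ...) {
  tibble(endpoint = x$endpoint, chisq = x$chisq, p_value = x$p_value,
         method = x$method, n_high = unname(x$n[1]), n_low = unname(x$n[2]))
}

#' Tidy a LOOCV report
#'
#' @param x A `loocv_report` from [loocv_sweep()].
#' @param ... Unused.
#' @return Tibble `size`, `errors`.
#' @export
tidy.loocv_report <- function(x, ...) as_tibble(x)[, c("size", "errors")]

#' @rdname tidy.loocv_report
#' @export
glance.loocv_report <- function(x, ...) {
  best <- attr(x, "best_sizes")
  tibble(n_sizes = nrow(x), min_errors = min(x$errors),
         best_size_smallest = min(best), best_size_largest = max(best))
}

#' Tidy a permutation null
#'
#' @param x A `perm_null` from [permutation_null()].
#' @param ... Unused.
#' @return Tibble `trial`, `n_passing`.
#' @export
tidy.perm_null <- function(x, ...) {
  tibble(trial = seq_along(x$null_counts), n_passing = x$null_counts)
}

#' @rdname tidy.perm_null
#' @export
glance.perm_null <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value,
         r_threshold = x$r_threshold, n_permutations = x$n_permutations)
}
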