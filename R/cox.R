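#' Normalise expression by the housekeeping geometric mean
#'
#' Divides every sample's expression column by the geometric mean of that
#' sample's housekeeping-gene values (TFRC, GUSB and RPLP0 by default),
#' yielding relative expression that is invariant to per-sample scaling
#' (sequencing depth, array intensity).  A pseudocount is added to the
#' housekeeping values before the geometric mean so isolated zeros do not
#' annihilate it; a sample whose housekeeping values are all zero is an
#' error.
#'
#' @param expr Genes x samples matrix of non-negative expression
#'   (RPKM-like or probe intensities).
#' @param housekeeping Housekeeping gene identifiers; at least one must be
#'   present in `expr`.
#' @param pseudocount Added to housekeeping values before the geometric
#'   mean (default 0.01).
#' @return The normalised matrix (housekeeping rows retained), with the
#'   per-sample divisors in `attr(, "size_factors")`.
#' @export
housekeeping_normalize <- function(expr, housekeeping = c("TFRC", "GUSB", "RPLP0"),
                                   pseudocount = 0.01) {
  check_expression(expr)
  hk <- intersect(housekeeping, rownames(expr))
  if (!length(hk)) {
    abort(sprintf("none of the housekeeping genes (%s) are in the matrix.",
                  paste(housekeeping, collapse = ", ")))
  }
  hkv <- expr[hk, , drop = FALSE]
  dead <- colnames(expr)[colSums(hkv) == 0]
  if (length(dead)) {
    abort(sprintf("all housekeeping values are zero in sample(s): %s",
                  paste(head(dead, 5), collapse = ", ")))
  }
  sf <- apply(hkv + pseudocount, 2L, geometric_mean)
  out <- sweep(expr, 2L, sf, "/")
  attr(out, "size_factors") <- sf
  attr(out, "housekeeping") <- hk
  attr(out, "pseudocount") <- pseudocount
  out
}

# Single-covariate Cox fit; returns coef, p, status.
cox_one_gene <- function(surv, x) {
  if (sd(x) == 0) {
    return(list(coef = NA_real_, p = NA_real_, status = "constant"))
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(surv ~ x, ties = "efron")),
    error = function(e) NULL
  )
  if (is.null(fit) || is.na(stats::coef(fit))) {
    return(list(coef = NA_real_, p = NA_real_, status = "failed"))
  }
  s <- summary(fit)
  list(coef = unname(stats::coef(fit)), p = unname(s$coefficients[1, "Pr(>|z|)"]),
       status = if (fit$iter >= 20) "nonconverged" else "ok")
}

#' Rank genes by univariate Cox regression
#'
#' Fits one proportional-hazards model per gene (single covariate, Efron tie
#' handling) against the chosen survival endpoint and orders genes by Wald
#' p-value ascending; ties break by |coefficient| descending, then gene
#' identifier.  Genes whose fit is degenerate (constant expression) or fails
#' are placed last with a status flag.
#'
#' @param expr Genes x samples matrix, typically housekeeping-normalised.
#' @param clinical Clinical tibble covering the samples of `expr`.
#' @param endpoint One of `"os"`, `"dss"`, `"dfs"`, `"rfs"` (default dfs).
#' @param genes Genes to rank (default all rows).
#' @param log2 Fit on `log2(expression + 1)` (default FALSE).
#' @return A tibble `gene`, `coef`, `p_value`, `status`, in rank order.
#' @export
univariate_rank <- function(expr, clinical, endpoint = "dfs", genes = NULL,
                            log2 = FALSE) {
  check_expression(expr)
  genes <- genes %||% rownames(expr)
  if (log2) expr <- log2(expr + 1)
  rec <- reconcile_samples(expr[genes, , drop = FALSE], clinical, quiet = TRUE)
  cols <- endpoint_cols(endpoint)
  if (sum(rec$clinical[[cols["event"]]]) < 1) abort("no events in the training data.")
  surv <- endpoint_surv(rec$clinical, endpoint)
  fits <- purrr::map(genes, function(g) {
    f <- cox_one_gene(surv, rec$expr[g, ])
    tibble(gene = g, coef = f$coef, p_value = f$p, status = f$status)
  })
  bind_rows(fits) |>
    mutate(.ok = .data$status %in% c("ok", "nonconverged")) |>
    arrange(desc(.data$.ok), .data$p_value, desc(abs(.data$coef)), .data$gene) |>
    select(-".ok")
}

# Multivariate Cox fit with a ridge-stabilised fallback.
cox_multi <- function(surv, xmat) {
  fit <- tryCatch(
    suppressWarnings(survival::coxph(surv ~ xmat, ties = "efron")),
    error = function(e) NULL
  )
  status <- "ok"
  if (is.null(fit) || any(is.na(stats::coef(fit)))) {
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv ~ survival::ridge(xmat, theta = 0.1),
                                       ties = "efron")),
      error = function(e) NULL
    )
    status <- "ridge"
  }
  if (is.null(fit) || any(is.na(stats::coef(fit)))) return(list(beta = NULL, status = "failed"))
  list(beta = setNames(unname(stats::coef(fit)), colnames(xmat)), status = status)
}

#' Grow a weighted Cox signature by forward addition
#'
#' Starting from the top of a univariate Cox ranking, adds one gene at a
#' time to a multivariate proportional-hazards model fitted on the training
#' samples.  At each size k the fitted coefficients score the test samples
#' (risk score = sum of coefficient times normalised expression), the test
#' cohort is split at its own median score (scores strictly below the
#' median are low risk), and the two-group Kaplan-Meier log-rank p-value is
#' recorded.  The selected signature is the k minimising this test-set
#' KM p-value (smallest k on ties).  Non-converging fits are retried with a
#' small ridge penalty; a size whose fit still fails is skipped.
#'
#' @param expr Normalised genes x samples matrix covering train and test
#'   samples.
#' @param clinical Clinical tibble.
#' @param train_ids,test_ids Sample identifiers of the two arms.
#' @param ranking A [univariate_rank()] tibble (or character vector of genes
#'   in rank order).
#' @param max_k Largest signature size to try (default 118, capped at the
#'   ranking length with a warning).
#' @param endpoint Survival endpoint (default `"dfs"`).
#' @param split_median Use the `"test"` population's own median (default)
#'   or the `"train"` median for the KM split.
#' @param log2 Fit and score on `log2(expression + 1)`; the flag is stored
#'   in the signature so downstream scoring applies the same transform.
#' @return A `weighted_signature` object: list with `genes` (tibble `gene`,
#'   `beta`), `endpoint`, `housekeeping`, `pseudocount`, `trace` (the
#'   per-k `selection trace`: `k`, `gene_added`, `fit_status`, `km_p`),
#'   `k_selected`, and training metadata.
#' @export
forward_cox_select <- function(expr, clinical, train_ids, test_ids, ranking,
                               max_k = 118, endpoint = "dfs",
                               split_median = c("test", "train"),
                               log2 = FALSE) {
  check_expression(expr)
  split_median <- match.arg(split_median)
  genes <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  if (!length(genes)) abort("`ranking` is empty.")
  if (max_k > length(genes)) {
    warn(sprintf("max_k = %d exceeds the %d ranked genes; truncated.",
                 max_k, length(genes)))
    max_k <- length(genes)
  }
  cl <- clinical[match(c(train_ids, test_ids), clinical$sample_id), , drop = FALSE]
  if (anyNA(cl$sample_id)) abort("train/test ids missing from the clinical table.")
  cl_train <- cl[seq_along(train_ids), , drop = FALSE]
  cl_test <- cl[length(train_ids) + seq_along(test_ids), , drop = FALSE]
  surv_train <- endpoint_surv(cl_train, endpoint)
  x_train <- t(expr[genes[seq_len(max_k)], train_ids, drop = FALSE])
  x_test <- t(expr[genes[seq_len(max_k)], test_ids, drop = FALSE])
  if (log2) {
    x_train <- log2(x_train + 1)
    x_test <- log2(x_test + 1)
  }

  rows <- vector("list", max_k)
  best <- list(k = NA_integer_, p = Inf, beta = NULL)
  for (k in seq_len(max_k)) {
    fit <- cox_multi(surv_train, x_train[, seq_len(k), drop = FALSE])
    if (fit$status == "failed") {
      rows[[k]] <- tibble(k = k, gene_added = genes[k], fit_status = "failed",
                          km_p = NA_real_)
      next
    }
    score <- as.vector(x_test[, seq_len(k), drop = FALSE] %*% fit$beta)
    ref <- if (split_median == "test") score else
      as.vector(x_train[, seq_len(k), drop = FALSE] %*% fit$beta)
    group <- ifelse(score < median(ref), "low", "high")
    km_p <- if (length(unique(group)) < 2L) NA_real_ else {
      sd <- survival::survdiff(endpoint_surv(cl_test, endpoint) ~ group)
      pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    }
    rows[[k]] <- tibble(k = k, gene_added = genes[k], fit_status = fit$status,
                        km_p = km_p)
    if (!is.na(km_p) && km_p < best$p) best <- list(k = k, p = km_p, beta = fit$beta)
  }
  trace <- bind_rows(rows)
  if (is.na(best$k)) abort("no signature size produced a usable fit and KM split.")
  structure(
    list(genes = tibble(gene = genes[seq_len(best$k)], beta = unname(best$beta)),
         endpoint = endpoint,
         housekeeping = attr(expr, "housekeeping") %||% c("TFRC", "GUSB", "RPLP0"),
         pseudocount = attr(expr, "pseudocount") %||% 0.01,
         log2 = log2,
         k_selected = best$k,
         km_p = best$p,
         trace = trace,
         n_train = length(train_ids), n_test = length(test_ids)),
    class = "weighted_signature"
  )
}

#' @export
print.weighted_signature <- function(x, ...) {
  cat(sprintf("<weighted_signature> %d genes (endpoint %s, test KM log-rank p = %.3g)\n",
              nrow(x$genes), toupper(x$endpoint), x$km_p))
  cat(sprintf("  normalisation: geometric mean of %s (pseudocount %g)\n",
              paste(x$housekeeping, collapse = ", "), x$pseudocount))
  print(x$genes, n = 12)
  invisible(x)
}

#' Write or read a weighted signature as structured text
#'
#' The file is a small key-value header (`endpoint`, `housekeeping`,
#' `pseudocount`, `k_selected`) followed by a `gene<TAB>beta` block.
#' Coefficients are written with 17 significant digits, so a save/load
#' round-trip reproduces risk scores exactly.
#'
#' @param signature A `weighted_signature`.
#' @param path File path.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   returns the `weighted_signature`.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "weighted_signature"))
  header <- c(
    paste0("#endpoint=", signature$endpoint),
    paste0("#housekeeping=", paste(signature$housekeeping, collapse = ",")),
    paste0("#pseudocount=", sprintf("%.17g", signature$pseudocount)),
    paste0("#log2=", as.integer(isTRUE(signature$log2))),
    paste0("#k_selected=", signature$k_selected),
    "gene\tbeta"
  )
  body <- sprintf("%s\t%.17g", signature$genes$gene, signature$genes$beta)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^#", key, "="), "", grep(paste0("^#", key, "="), hdr, value = TRUE))
  body <- lines[!grepl("^#", lines)][-1]  # drop the gene/beta header
  fields <- strsplit(body, "\t", fixed = TRUE)
  structure(
    list(genes = tibble(gene = vapply(fields, `[`, "", 1L),
                        beta = as.numeric(vapply(fields, `[`, "", 2L))),
         endpoint = get("endpoint"),
         housekeeping = strsplit(get("housekeeping"), ",")[[1]],
         pseudocount = as.numeric(get("pseudocount")),
         log2 = length(get("log2")) && get("log2") == "1",
         k_selected = as.integer(get("k_selected")),
         km_p = NA_real_, trace = NULL, n_train = NA, n_test = NA),
    class = "weighted_signature"
  )
}
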