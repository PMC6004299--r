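#' Collapse microarray probes to genes by best Cox probe
#'
#' For genes measured by several probes, keeps the probe whose univariate
#' Cox p-value against the chosen endpoint is smallest (ties broken by probe
#' identifier), mirroring how validation cohorts on probe-level platforms
#' are reduced to one row per gene.
#'
#' @param probe_expr Probes x samples matrix.
#' @param probe_map Tibble/data frame with columns `probe_id`, `gene`.
#' @param clinical Clinical tibble (for the per-probe Cox fits).
#' @param endpoint Survival endpoint (default `"os"`).
#' @param required_genes If given, error when any of these genes has no
#'   probe.
#' @return Genes x samples matrix; the probe chosen per gene is recorded in
#'   `attr(, "chosen_probes")`.
#' @export
collapse_probes <- function(probe_expr, probe_map, clinical, endpoint = "os",
                            required_genes = NULL) {
  check_expression(probe_expr)
  stopifnot(all(c("probe_id", "gene") %in% names(probe_map)))
  probe_map <- probe_map |> filter(.data$probe_id %in% rownames(probe_expr))
  if (!is.null(required_genes)) {
    missing <- setdiff(required_genes, probe_map$gene)
    if (length(missing)) {
      abort(sprintf("signature gene(s) with no probe: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  rec <- reconcile_samples(probe_expr, clinical, quiet = TRUE)
  surv <- endpoint_surv(rec$clinical, endpoint)
  choice <- probe_map |>
    mutate(p_value = purrr::map_dbl(.data$probe_id, function(p) {
      f <- cox_one_gene(surv, rec$expr[p, ])
      if (is.na(f$p)) Inf else f$p
    })) |>
    arrange(.data$gene, .data$p_value, .data$probe_id) |>
    group_by(.data$gene) |>
    dplyr::slice(1L) |>
    ungroup()
  out <- probe_expr[choice$probe_id, , drop = FALSE]
  rownames(out) <- choice$gene
  attr(out, "chosen_probes") <- choice |> select("gene", "probe_id", "p_value")
  out
}

#' Score a cohort with a weighted signature and split at the median
#'
#' Computes each sample's risk score as the weighted sum of its
#' housekeeping-normalised (relative) expression over the signature genes,
#' score = sum_i E_i * beta_i, then dichotomises the cohort at the
#' population median: scores strictly below the median are low risk, the
#' rest high risk.  Missing signature genes are an error; nothing is
#' imputed.
#'
#' @param expr Genes x samples matrix of raw (un-normalised) expression;
#'   the signature's own housekeeping rule is applied internally.
#' @param signature A `weighted_signature` (from [forward_cox_select()] or
#'   [read_signature()]).
#' @param normalize Set `FALSE` if `expr` is already relative expression.
#' @return A `risk_scores` tibble: `sample_id`, `score`, `group`
#'   (high/low).  Degenerate splits (all scores equal) are flagged via
#'   `attr(, "degenerate")`.
#' @export
score_cohort <- function(expr, signature, normalize = TRUE) {
  check_expression(expr)
  stopifnot(inherits(signature, "weighted_signature"))
  missing <- setdiff(signature$genes$gene, rownames(expr))
  if (length(missing)) {
    abort(sprintf("signature gene(s) missing from the cohort: %s",
                  paste(missing, collapse = ", ")))
  }
  if (normalize) {
    expr <- housekeeping_normalize(expr, signature$housekeeping,
                                   signature$pseudocount)
  }
  e <- expr[signature$genes$gene, , drop = FALSE]
  if (isTRUE(signature$log2)) e <- log2(e + 1)
  score <- as.vector(crossprod(e, signature$genes$beta))
  degenerate <- length(unique(score)) == 1L
  if (degenerate) {
    warn("all risk scores are identical; median split is degenerate (all high).")
  }
  out <- tibble(sample_id = colnames(expr), score = score,
                group = factor(median_split(score), levels = c("high", "low")))
  class(out) <- c("risk_scores", class(out))
  attr(out, "degenerate") <- degenerate
  out
}

#' Kaplan-Meier comparison of high- vs low-risk groups
#'
#' Product-limit curves per risk group and the two-sample log-rank test
#' (chi-squared approximation, df = 1) for a named survival endpoint.  For
#' very small strata an exact permutation log-rank p-value is available.
#'
#' @param scores A `risk_scores` tibble (or any tibble with `sample_id` and
#'   a two-level `group`).
#' @param clinical Clinical tibble with the endpoint columns.
#' @param endpoint One of `"os"`, `"dss"`, `"dfs"`, `"rfs"`.
#' @param method `"chisq"` (default) or `"permutation"`; the latter permutes
#'   group labels `n_perm` times and uses the add-one estimator.
#' @param n_perm Permutations when `method = "permutation"`.
#' @param seed Seed for the permutation method.
#' @return A `survival_comparison`: list with `endpoint`, `n` (per group),
#'   `chisq`, `p_value`, `method`, and `curves` (tibble `group`, `time`,
#'   `survival`, `n_risk`, `n_event`).
#' @export
km_logrank <- function(scores, clinical, endpoint = "os",
                       method = c("chisq", "permutation"),
                       n_perm = 2000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(c("sample_id", "group") %in% names(scores)))
  cl <- clinical[match(scores$sample_id, clinical$sample_id), , drop = FALSE]
  if (anyNA(cl$sample_id)) abort("scored sample(s) missing from the clinical table.")
  group <- droplevels(factor(scores$group))
  if (nlevels(group) < 2L) abort("both risk groups must be non-empty.")
  surv <- endpoint_surv(cl, endpoint)
  if (sum(cl[[endpoint_cols(endpoint)["event"]]]) < 1) {
    abort("no events for this endpoint.")
  }
  sd <- survival::survdiff(surv ~ group)
  chisq <- sd$chisq
  if (method == "chisq") {
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  } else {
    set.seed(seed)
    exceed <- sum(vapply(seq_len(n_perm), function(i) {
      survival::survdiff(surv ~ sample(group))$chisq >= chisq - 1e-12
    }, logical(1)))
    p <- (exceed + 1) / (n_perm + 1)
  }
  fit <- survival::survfit(surv ~ group)
  sfit <- summary(fit, censored = TRUE)
  strata <- if (is.null(sfit$strata)) rep(levels(group)[1], length(sfit$time)) else
    sub("^group=", "", as.character(sfit$strata))
  curves <- tibble(group = strata, time = sfit$time, survival = sfit$surv,
                   n_risk = sfit$n.risk, n_event = sfit$n.event)
  structure(
    list(endpoint = endpoint,
         n = table(group),
         chisq = chisq,
         p_value = p,
         method = method,
         curves = curves),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<survival_comparison> %s: log-rank chisq = %.3f, p = %.4g (%s; n = %s)\n",
              toupper(x$endpoint), x$chisq, x$p_value, x$method,
              paste(sprintf("%s %d", names(x$n), x$n), collapse = ", ")))
  invisible(x)
}

#' Stratified survival comparisons
#'
#' Runs a battery of Kaplan-Meier/log-rank comparisons inside clinical
#' strata: within each stratum (a set of filters on clinical covariates)
#' either the high- vs low-score groups are compared (`compare = "group"`),
#' or adjuvant-chemotherapy vs no-chemotherapy arms are compared within one
#' score group (`compare = "act"`, with `within` naming the group), which is
#' the treatment-interaction question.  Samples with unknown values for a
#' filtering covariate are excluded from that stratum; strata with an empty
#' arm are skipped with a recorded reason.
#'
#' @param scores A `risk_scores` tibble.
#' @param clinical Clinical tibble (must carry the strata covariates).
#' @param strata_spec A list of stratum definitions; each is a list with
#'   `name`, optional `filter` (named list, e.g.
#'   `list(stage = c("II","III"), mmr_status = "pMMR", act_flag = TRUE)`),
#'   optional `endpoint` (default `"os"`), optional `compare`
#'   (`"group"`/`"act"`), optional `within` (`"high"`/`"low"`, for
#'   `compare = "act"`).
#' @return Tibble: `analysis`, `endpoint`, `compare`, `filter`, `n1`, `n2`,
#'   `chisq`, `p_value`, `skipped`, `reason`, and a `comparison`
#'   list-column with the full [km_logrank()] objects.
#' @export
stratified_analysis <- function(scores, clinical, strata_spec) {
  stopifnot(is.list(strata_spec))
  dat <- scores |>
    left_join(clinical, by = "sample_id")
  rows <- purrr::map(strata_spec, function(spec) {
    name <- spec$name %||% "stratum"
    endpoint <- spec$endpoint %||% "os"
    compare <- spec$compare %||% "group"
    filt <- spec$filter %||% list()
    d <- dat
    for (v in names(filt)) {
      d <- d |> filter(!is.na(.data[[v]]), .data[[v]] %in% filt[[v]])
    }
    desc <- if (length(filt)) {
      paste(purrr::imap_chr(filt, ~ paste0(.y, "=", paste(.x, collapse = "|"))),
            collapse = ", ")
    } else "all"
    skip <- function(reason) {
      tibble(analysis = name, endpoint = endpoint, compare = compare,
             filter = desc, n1 = NA_integer_, n2 = NA_integer_,
             chisq = NA_real_, p_value = NA_real_, skipped = TRUE,
             reason = reason, comparison = list(NULL))
    }
    if (!nrow(d)) return(skip("no samples match the stratum"))
    if (compare == "act") {
      d <- d |> filter(.data$group == (spec$within %||% "low"))
      if (!nrow(d)) return(skip("score group empty in stratum"))
      arm <- factor(ifelse(d$act_flag, "act", "control"))
    } else {
      arm <- droplevels(d$group)
    }
    if (nlevels(arm) < 2L || min(table(arm)) < 1L) {
      return(skip("an arm of the comparison is empty"))
    }
    cmp <- tryCatch(
      km_logrank(tibble(sample_id = d$sample_id, group = arm), clinical,
                 endpoint = endpoint),
      error = function(e) NULL
    )
    if (is.null(cmp)) return(skip("log-rank test failed (e.g. no events)"))
    tibble(analysis = name, endpoint = endpoint, compare = compare,
           filter = desc, n1 = unname(cmp$n[1]), n2 = unname(cmp$n[2]),
           chisq = cmp$chisq, p_value = cmp$p_value, skipped = FALSE,
           reason = NA_character_, comparison = list(cmp))
  })
  bind_rows(rows)
}

#' Stage enrichment between score groups
#'
#' Cross-tabulates risk group (high/low) against early (I & II) vs advanced
#' (III & IV) stage and tests association with a two-sided Fisher exact
#' test.  Samples with unknown stage are excluded and counted.
#'
#' @param scores A `risk_scores` tibble.
#' @param clinical Clinical tibble with a `stage` column (values I..IV,
#'   optionally with substage suffixes).
#' @return A `contingency_result`: list with `table` (2x2 counts), `test`,
#'   `p_value`, `n_unknown`.
#' @export
stage_enrichment <- function(scores, clinical) {
  d <- scores |> left_join(clinical, by = "sample_id")
  stage <- toupper(sub("^STAGE\\s*", "", toupper(as.character(d$stage))))
  stage_num <- dplyr::case_when(
    grepl("^IV", stage) ~ 4L, grepl("^III", stage) ~ 3L,
    grepl("^II", stage) ~ 2L, grepl("^I", stage) ~ 1L,
    .default = NA_integer_
  )
  known <- !is.na(stage_num)
  advanced <- factor(ifelse(stage_num[known] >= 3L, "III & IV", "I & II"),
                     levels = c("I & II", "III & IV"))
  tab <- table(group = droplevels(d$group[known]), stage = advanced)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("a margin of the stage-enrichment table is zero; p set to 1.")
    p <- 1
  } else {
    p <- fisher.test(tab)$p.value
  }
  structure(
    list(table = tab, test = "Fisher exact (two-sided)", p_value = p,
         n_unknown = sum(!known)),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> %s, p = %.4g (%d unknown excluded)\n",
              x$test, x$p_value, x$n_unknown))
  print(x$table)
  invisible(x)
}
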