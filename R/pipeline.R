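#' Configuration for the end-to-end signature pipeline
#'
#' Collects every stage's tunables with the pipeline's defaults: a 3-year
#' relapse horizon for prognosis grouping, a 0.3 correlation screen with a
#' Monte-Carlo null, even nested signature sizes for LOOCV with the
#' largest-minimiser selection rule, a balanced half/half scoring-phase
#' split, TFRC/GUSB/RPLP0 housekeeping normalisation, and forward Cox
#' selection up to 118 genes on the DFS endpoint.
#'
#' @param horizon_years Prognosis dichotomisation horizon (years).
#' @param phase1_n_poor,phase1_n_good Training class sizes for the discovery
#'   split; `NULL` takes 75% of each class.
#' @param r_threshold Correlation screen cutoff.
#' @param n_permutations Monte-Carlo trials for the screen null.
#' @param loocv_max_genes Cap on ranked genes entering the LOOCV sweep.
#' @param size_select How to pick the signature size among the LOOCV error
#'   minimisers: `"largest-min"` (default), `"smallest-min"`, or `"fixed"`
#'   (uses `fixed_size`).
#' @param fixed_size Size used when `size_select = "fixed"`.
#' @param phase2_fraction Training fraction of the scoring-phase split.
#' @param housekeeping Housekeeping genes for normalisation.
#' @param pseudocount Pseudocount for the housekeeping geometric mean.
#' @param max_k Largest multivariate signature size to try.
#' @param endpoint Survival endpoint driving Phase II (default `"dfs"`).
#' @param log2 Screen, fit and score on `log2(x + 1)`-transformed values
#'   (default FALSE: values as provided).
#' @param seed Global seed; per-stage sub-seeds are derived from it
#'   deterministically.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(horizon_years = 3,
                            phase1_n_poor = NULL, phase1_n_good = NULL,
                            r_threshold = 0.3, n_permutations = 2000,
                            loocv_max_genes = 200,
                            size_select = c("largest-min", "smallest-min", "fixed"),
                            fixed_size = NULL,
                            phase2_fraction = 0.5,
                            housekeeping = c("TFRC", "GUSB", "RPLP0"),
                            pseudocount = 0.01,
                            max_k = 118, endpoint = "dfs", log2 = FALSE,
                            seed = 1L) {
  size_select <- match.arg(size_select)
  if (size_select == "fixed" && is.null(fixed_size)) {
    abort("`fixed_size` is required when size_select = \"fixed\".")
  }
  structure(
    list(horizon_years = horizon_years, phase1_n_poor = phase1_n_poor,
         phase1_n_good = phase1_n_good, r_threshold = r_threshold,
         n_permutations = n_permutations, loocv_max_genes = loocv_max_genes,
         size_select = size_select, fixed_size = fixed_size,
         phase2_fraction = phase2_fraction, housekeeping = housekeeping,
         pseudocount = pseudocount, max_k = max_k, endpoint = endpoint,
         log2 = log2, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full two-phase signature pipeline
#'
#' Executes prognosis grouping, the correlation screen (with permutation
#' null), the LOOCV signature-size sweep, forward Cox selection, and
#' cohort validation in order, wiring each stage's outputs to the next.  A
#' single seed governs every stochastic step, every output file is written
#' under `out_dir`, and the returned manifest records each file's MD5
#' digest so reruns can be checked for bit-identical provenance.
#'
#' @param expr Genes x samples matrix, or path to an expression TSV.
#' @param clinical Clinical tibble, or path to a clinical TSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return A `run_manifest`: tibble `stage`, `file`, `md5`, with the
#'   resolved configuration in `attr(, "config")`, accumulated warnings in
#'   `attr(, "warnings")`, and key per-stage results in
#'   `attr(, "results")`.
#' @export
run_full_pipeline <- function(expr, clinical, out_dir,
                              config = pipeline_config()) {
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  check_expression(expr)
  check_clinical(clinical)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- tibble(stage = character(), file = character(), md5 = character())
  warnings <- character()
  results <- list()
  stage <- "init"
  record <- function(stg, path) {
    manifest <<- bind_rows(manifest,
                           tibble(stage = stg, file = basename(path),
                                  md5 = unname(tools::md5sum(path))))
  }
  run <- withCallingHandlers(
    tryCatch({
      rec <- reconcile_samples(expr, clinical)
      expr <- rec$expr
      clinical <- rec$clinical

      # -- prep ---------------------------------------------------------
      stage <- "prep"
      labels <- assign_prognosis_labels(clinical, config$horizon_years)
      counts <- attr(labels, "counts")
      n_poor <- config$phase1_n_poor %||% floor(0.75 * counts[["poor"]])
      n_good <- config$phase1_n_good %||% floor(0.75 * counts[["good"]])
      split1 <- split_phase1(labels, n_poor, n_good, seed = config$seed + 101L)
      p <- file.path(out_dir, "labels.tsv")
      readr::write_tsv(split1, p, progress = FALSE); record(stage, p)
      results$labels <- labels
      results$split1 <- split1

      # -- screen -------------------------------------------------------
      stage <- "screen"
      train_lab <- split1 |> filter(.data$set == "train")
      cors <- gene_prognosis_correlation(expr, train_lab, log2 = config$log2)
      ranked <- screen_genes(cors, config$r_threshold)
      if (nrow(ranked) < 2L) abort("screen retained fewer than 2 genes.")
      null <- permutation_null(expr, train_lab, config$r_threshold,
                               config$n_permutations,
                               seed = config$seed + 202L, log2 = config$log2)
      p <- file.path(out_dir, "ranked_genes.tsv")
      readr::write_tsv(ranked, p, progress = FALSE); record(stage, p)
      p <- file.path(out_dir, "permutation_null.tsv")
      readr::write_tsv(tibble(trial = seq_along(null$null_counts),
                              n_passing = null$null_counts), p, progress = FALSE)
      record(stage, p)
      results$screen <- ranked
      results$null <- null

      # -- loocv --------------------------------------------------------
      stage <- "loocv"
      genes_cv <- head(ranked$gene, config$loocv_max_genes)
      cv <- loocv_sweep(expr, train_lab, genes_cv)
      best <- attr(cv, "best_sizes")
      k1 <- switch(config$size_select,
                   "largest-min" = max(best),
                   "smallest-min" = min(best),
                   "fixed" = config$fixed_size)
      phase1_genes <- head(ranked$gene, k1)
      p <- file.path(out_dir, "loocv_errors.tsv")
      readr::write_tsv(cv |> select("size", "errors"), p, progress = FALSE)
      record(stage, p)
      roc <- roc_compare(
        setNames(list(risk_coef(scale_rows(expr[, split1$sample_id]),
                                build_templates(scale_rows(expr[, split1$sample_id]),
                                                train_lab, phase1_genes))),
                 sprintf("%d-gene", k1)),
        split1)
      p <- file.path(out_dir, "roc_auc.tsv")
      readr::write_tsv(roc |> select(-"curve"), p, progress = FALSE)
      record(stage, p)
      results$loocv <- cv
      results$phase1_genes <- phase1_genes
      results$roc <- roc

      # -- cox-select ---------------------------------------------------
      stage <- "cox-select"
      norm <- housekeeping_normalize(expr, config$housekeeping, config$pseudocount)
      split2 <- split_phase2(clinical, config$phase2_fraction,
                             seed = config$seed + 303L)
      train2 <- split2$sample_id[split2$set == "train"]
      test2 <- split2$sample_id[split2$set == "test"]
      ranking <- univariate_rank(norm[, train2, drop = FALSE],
                                 clinical, config$endpoint,
                                 genes = setdiff(phase1_genes, config$housekeeping),
                                 log2 = config$log2)
      sig <- forward_cox_select(norm, clinical, train2, test2, ranking,
                                max_k = min(config$max_k, nrow(ranking)),
                                endpoint = config$endpoint, log2 = config$log2)
      p <- file.path(out_dir, "signature.txt")
      write_signature(sig, p); record(stage, p)
      p <- file.path(out_dir, "selection_trace.tsv")
      readr::write_tsv(sig$trace, p, progress = FALSE); record(stage, p)
      results$signature <- sig
      results$split2 <- split2

      # -- validate -----------------------------------------------------
      stage <- "validate"
      scores <- score_cohort(expr, sig)
      comparisons <- purrr::map(setNames(.endpoints, .endpoints), function(ep) {
        tryCatch(km_logrank(scores, clinical, ep), error = function(e) NULL)
      })
      km_tbl <- bind_rows(purrr::imap(comparisons, function(cmp, ep) {
        if (is.null(cmp)) return(tibble())
        tibble(endpoint = ep, chisq = cmp$chisq, p_value = cmp$p_value)
      }))
      enrich <- stage_enrichment(scores, clinical)
      p <- file.path(out_dir, "risk_scores.tsv")
      readr::write_tsv(scores, p, progress = FALSE); record(stage, p)
      p <- file.path(out_dir, "validation_km.tsv")
      readr::write_tsv(km_tbl, p, progress = FALSE); record(stage, p)
      p <- file.path(out_dir, "stage_enrichment.tsv")
      readr::write_tsv(tibble(cell = c("high_early", "high_advanced",
                                       "low_early", "low_advanced"),
                              count = as.vector(t(enrich$table)),
                              p_value = enrich$p_value), p, progress = FALSE)
      record(stage, p)
      results$scores <- scores
      results$validation <- comparisons
      results$stage_enrichment <- enrich
      TRUE
    }, error = function(e) e),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  # resolved config + manifest are themselves outputs
  cfgp <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfgp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  manifest <- bind_rows(manifest, tibble(stage = "config", file = "config.json",
                                         md5 = unname(tools::md5sum(cfgp))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(manifest) <- c("run_manifest", class(manifest))
  attr(manifest, "config") <- config
  attr(manifest, "warnings") <- warnings
  attr(manifest, "results") <- results
  if (inherits(run, "error")) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(run)),
          parent = run)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d files from %d stages\n",
              nrow(x), length(unique(x$stage))))
  print(as_tibble(x))
  w <- attr(x, "warnings")
  if (length(w)) cat(sprintf("warnings (%d): %s\n", length(w),
                             paste(head(w, 3), collapse = " | ")))
  invisible(x)
}
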