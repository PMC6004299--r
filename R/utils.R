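# Internal helpers shared across modules.

# Validate a genes x samples expression matrix.
check_expression <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples).", arg))
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(expr))) {
    abort(sprintf("`%s` has duplicated gene identifiers; collapse probes first.", arg))
  }
  if (anyDuplicated(colnames(expr))) {
    abort(sprintf("`%s` has duplicated sample identifiers.", arg))
  }
  invisible(expr)
}

check_clinical <- function(clinical, cols = "sample_id") {
  if (!is.data.frame(clinical)) abort("`clinical` must be a data frame.")
  missing <- setdiff(cols, names(clinical))
  if (length(missing)) {
    abort(sprintf("`clinical` is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(clinical$sample_id)) abort("`clinical` has duplicated sample ids.")
  invisible(clinical)
}

# Columns holding an endpoint's event indicator and time.
endpoint_cols <- function(endpoint) {
  endpoint <- match.arg(tolower(endpoint), .endpoints)
  c(event = paste0(endpoint, "_event"), time = paste0(endpoint, "_time"))
}

# Survival object for an endpoint from a clinical tibble (times in years).
endpoint_surv <- function(clinical, endpoint) {
  cols <- endpoint_cols(endpoint)
  check_clinical(clinical, c("sample_id", cols))
  survival::Surv(clinical[[cols["time"]]], clinical[[cols["event"]]])
}

# Per-gene z-scoring across samples; zero-variance rows become all-zero.
scale_rows <- function(expr) {
  mu <- rowMeans(expr)
  s <- apply(expr, 1L, sd)
  z <- (expr - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

# Interpolated median split: strictly below the population median -> "low",
# the rest -> "high".
median_split <- function(scores) {
  m <- median(scores)
  ifelse(scores < m, "low", "high")
}

geometric_mean <- function(x) exp(mean(log(x)))

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
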