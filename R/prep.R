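#' Dichotomise patients by relapse status at a horizon
#'
#' Patients who relapsed within `horizon_years` of follow-up are labelled
#' poor prognosis; patients relapse-free for at least `horizon_years` are
#' good prognosis.  Relapse-free patients censored before the horizon are
#' excluded: their status at the horizon is unknowable.
#'
#' @param clinical Clinical tibble with `sample_id`, `dfs_event`, `dfs_time`.
#' @param horizon_years Dichotomisation horizon (default 3 years).
#' @param time_unit Unit of the stored times; `"days"` converts at 365.25
#'   days per year.
#' @return Tibble `sample_id`, `label` (factor poor/good/excluded), with the
#'   label counts in `attr(, "counts")`.
#' @examples
#' cl <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                      dfs_event = c(1L, 0L, 0L),
#'                      dfs_time = c(2.5, 4, 2))
#' assign_prognosis_labels(cl)  # poor, good, excluded
#' @export
assign_prognosis_labels <- function(clinical, horizon_years = 3,
                                    time_unit = c("years", "days")) {
  check_clinical(clinical, c("sample_id", "dfs_event", "dfs_time"))
  time_unit <- match.arg(time_unit)
  bad <- clinical$sample_id[is.na(clinical$dfs_event) | is.na(clinical$dfs_time)]
  if (length(bad)) {
    abort(sprintf("missing dfs_event/dfs_time for sample(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  t <- clinical$dfs_time / if (time_unit == "days") 365.25 else 1
  label <- dplyr::case_when(
    clinical$dfs_event == 1L & t < horizon_years ~ "poor",
    t >= horizon_years ~ "good",
    .default = "excluded"
  )
  out <- tibble(sample_id = clinical$sample_id,
                label = factor(label, levels = c("poor", "good", "excluded")))
  attr(out, "counts") <- table(out$label)
  attr(out, "horizon_years") <- horizon_years
  out
}

#' Draw the discovery-phase training/test split
#'
#' Samples a fixed number of poor- and good-prognosis patients (without
#' replacement, under `seed`) into the training set; all remaining labelled
#' patients form the test set.  Excluded patients belong to neither.
#'
#' @param labels Output of [assign_prognosis_labels()].
#' @param n_poor_train,n_good_train Training-set class sizes (defaults 32
#'   and 39).
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `label`, `set` (train/test) covering the
#'   poor/good patients only.
#' @export
split_phase1 <- function(labels, n_poor_train = 32, n_good_train = 39, seed = 1L) {
  stopifnot(all(c("sample_id", "label") %in% names(labels)))
  poor <- labels$sample_id[labels$label == "poor"]
  good <- labels$sample_id[labels$label == "good"]
  if (n_poor_train < 1 || n_good_train < 1) {
    abort("training class sizes must be at least 1.")
  }
  if (n_poor_train > length(poor) || n_good_train > length(good)) {
    abort(sprintf("requested %d poor / %d good training samples but only %d / %d available.",
                  n_poor_train, n_good_train, length(poor), length(good)))
  }
  set.seed(seed)
  train <- c(sample(poor, n_poor_train), sample(good, n_good_train))
  labels |>
    filter(.data$label != "excluded") |>
    mutate(label = droplevels(.data$label),
           set = factor(ifelse(.data$sample_id %in% train, "train", "test"),
                        levels = c("train", "test")))
}

#' Test clinicopathologic balance between two patient groups
#'
#' For each characteristic: numeric columns get a Welch two-sample t-test;
#' two-level categorical columns a two-sided Fisher exact test; categorical
#' columns with more than two levels a Pearson chi-squared test.  Missing
#' values are excluded from that characteristic's test only, and
#' characteristics with a single observed level are skipped with a reason.
#'
#' @param clinical_train,clinical_test Clinical tibbles for the two arms.
#' @param vars Characteristics to test (default: age, sex, stage,
#'   mmr_status, act_flag, intersected with the available columns).
#' @return Tibble `characteristic`, `test`, `statistic`, `p_value`, `note`.
#' @examples
#' # Fisher two-sided p for a 2x2 split of sexes
#' a <- tibble::tibble(sample_id = as.character(1:119),
#'                     sex = rep(c("m", "f"), c(60, 59)))
#' b <- tibble::tibble(sample_id = as.character(200:320),
#'                     sex = rep(c("m", "f"), c(54, 67)))
#' balance_tests(a, b, vars = "sex")
#' @export
balance_tests <- function(clinical_train, clinical_test,
                          vars = c("age", "sex", "stage", "mmr_status", "act_flag")) {
  vars <- intersect(vars, intersect(names(clinical_train), names(clinical_test)))
  if (!length(vars)) abort("no shared characteristics to test.")
  rows <- purrr::map(vars, function(v) {
    x <- clinical_train[[v]]
    y <- clinical_test[[v]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (is.numeric(x) && !is.logical(x) && length(unique(c(x, y))) > 5L) {
      tt <- t.test(x, y)
      return(tibble(characteristic = v, test = "Welch t-test",
                    statistic = unname(tt$statistic), p_value = tt$p.value,
                    note = NA_character_))
    }
    tab <- table(factor(c(x, y)), rep(c("train", "test"), c(length(x), length(y))))
    k <- nrow(tab)
    if (k < 2L) {
      return(tibble(characteristic = v, test = NA_character_,
                    statistic = NA_real_, p_value = NA_real_,
                    note = "skipped: single observed level"))
    }
    if (k == 2L) {
      ft <- fisher.test(tab)
      tibble(characteristic = v, test = "Fisher exact (two-sided)",
             statistic = NA_real_, p_value = ft$p.value, note = NA_character_)
    } else {
      ct <- suppressWarnings(chisq.test(tab))
      tibble(characteristic = v, test = "Pearson chi-squared",
             statistic = unname(ct$statistic), p_value = ct$p.value,
             note = NA_character_)
    }
  })
  bind_rows(rows)
}

#' Draw a balanced random split for the scoring phase
#'
#' Randomly splits the cohort at `fraction`, checks clinicopathologic
#' balance with [balance_tests()], and redraws (seeded, up to `max_retries`
#' times) until every balance p-value exceeds `p_threshold`.  If the retry
#' budget is exhausted a warning is raised and the best-balanced split found
#' is returned.
#'
#' @param clinical Clinical tibble.
#' @param fraction Training fraction in (0, 1); sizes use `floor(n * fraction)`.
#' @param seed Integer seed.
#' @param vars Characteristics passed to [balance_tests()].
#' @param p_threshold Minimum acceptable balance p-value (default 0.05).
#' @param max_retries Redraw budget (default 100).
#' @return Tibble `sample_id`, `set` (train/test); the accepted
#'   [balance_tests()] report is in `attr(, "balance")`, the number of draws
#'   in `attr(, "draws")`.
#' @export
split_phase2 <- function(clinical, fraction = 0.5, seed = 1L,
                         vars = c("age", "sex", "stage", "mmr_status", "act_flag"),
                         p_threshold = 0.05, max_retries = 100) {
  check_clinical(clinical)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be strictly between 0 and 1.")
  }
  n <- nrow(clinical)
  n_train <- floor(n * fraction)
  if (n_train < 1 || n_train >= n) abort("split leaves an empty arm.")
  set.seed(seed)
  best <- NULL
  best_min_p <- -Inf
  for (draw in seq_len(max_retries)) {
    train_idx <- sample.int(n, n_train)
    rep <- balance_tests(clinical[train_idx, ], clinical[-train_idx, ], vars = vars)
    min_p <- min(rep$p_value, na.rm = TRUE)
    if (min_p > best_min_p) {
      best_min_p <- min_p
      best <- list(idx = train_idx, report = rep, draws = draw)
    }
    if (min_p > p_threshold) break
  }
  if (best_min_p <= p_threshold) {
    warn(sprintf("no split with all balance p > %g found in %d draws; returning best (min p = %.3g).",
                 p_threshold, max_retries, best_min_p))
  }
  out <- tibble(sample_id = clinical$sample_id,
                set = factor(ifelse(seq_len(n) %in% best$idx, "train", "test"),
                             levels = c("train", "test")))
  attr(out, "balance") <- best$report
  attr(out, "draws") <- best$draws
  out
}
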