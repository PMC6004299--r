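mk_sig <- function(genes, beta, hk = c("TFRC", "GUSB", "RPLP0")) {
  structure(list(genes = tibble::tibble(gene = genes, beta = beta),
                 endpoint = "os", housekeeping = hk, pseudocount = 0.01,
                 k_selected = length(genes), km_p = NA_real_, trace = NULL,
                 n_train = NA, n_test = NA),
            class = "weighted_signature")
}

test_that("probe collapsing keeps the best-Cox probe per gene", {
  co <- simulate_cohort(sim_config(n_samples = 60, n_genes = 30,
                                   n_prognostic = 3, seed = 21))
  pm <- make_probe_matrix(co$expression, genes = rownames(co$expression)[1:5],
                          n_probes = 1, seed = 1)
  got <- collapse_probes(pm$probes, pm$map, co$clinical)
  expect_setequal(rownames(got), rownames(co$expression)[1:5])
  # single-probe genes keep their only probe's values
  expect_equal(got[1, ], pm$probes[paste0(rownames(got)[1], "_p1"), ])
  # probes with identical values tie-break by probe identifier
  dup <- rbind(a_p2 = co$expression[1, ], a_p1 = co$expression[1, ])
  map <- tibble::tibble(probe_id = c("a_p2", "a_p1"), gene = "a")
  cp <- collapse_probes(dup, map, co$clinical)
  expect_equal(attr(cp, "chosen_probes")$probe_id, "a_p1")
  expect_error(
    collapse_probes(dup, map, co$clinical, required_genes = c("a", "zz")),
    "zz")
})

test_that("prognostic probes beat decoy probes in collapsing", {
  wins <- sapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(n_samples = 150, n_genes = 40,
                                     n_prognostic = 6, effect_size = 1.2,
                                     seed = 300 + s))
    pm <- make_probe_matrix(co$expression, genes = co$truth$gene,
                            n_probes = 2, decoy = TRUE, seed = s)
    got <- collapse_probes(pm$probes, pm$map, co$clinical, endpoint = "dfs")
    chosen <- attr(got, "chosen_probes")
    mean(grepl("_p1$", chosen$probe_id))  # p1 is the real probe
  })
  expect_gte(mean(wins), 0.9)
})

test_that("risk scores follow the weighted-sum formula and median rule", {
  x <- matrix(c(1, 2, 2, 4, 3, 6, 4, 8), nrow = 2,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  sig <- mk_sig(c("gA", "gB"), c(0.5, -1))
  sc <- score_cohort(x, sig, normalize = FALSE)
  expect_equal(sc$score, c(0.5 * 1 - 1 * 2, -3, -4.5, -6))
  # scores (1,2,3,4): interpolated median 2.5; below it -> low
  x2 <- matrix(c(1, 2, 3, 4), nrow = 1, dimnames = list("gA", paste0("s", 1:4)))
  sc2 <- score_cohort(x2, mk_sig("gA", 1), normalize = FALSE)
  expect_equal(as.character(sc2$group), c("low", "low", "high", "high"))
  # zero signature: degenerate split flagged, all high by the tie rule
  expect_warning(sc0 <- score_cohort(x, mk_sig(c("gA", "gB"), c(0, 0)),
                                     normalize = FALSE), "degenerate")
  expect_true(attr(sc0, "degenerate"))
  expect_true(all(sc0$group == "high"))
  expect_error(score_cohort(x, mk_sig("gZ", 1), normalize = FALSE), "missing")
})

test_that("score_cohort is deterministic and independent of sample order", {
  co <- simulate_cohort(sim_config(n_samples = 50, n_genes = 40,
                                   n_prognostic = 4, seed = 22))
  sig <- mk_sig(co$truth$gene, rep(c(0.4, -0.4), 2))
  s1 <- score_cohort(co$expression, sig)
  perm <- sample(ncol(co$expression))
  s2 <- score_cohort(co$expression[, perm], sig)
  m <- match(s1$sample_id, s2$sample_id)
  expect_equal(s1$score, s2$score[m])
  expect_identical(as.character(s1$group), as.character(s2$group)[m])
})

test_that("log-rank statistic matches the O-E oracle on a textbook toy", {
  cl <- tibble::tibble(sample_id = paste0("s", 1:7),
                       os_event = rep(1L, 7),
                       os_time = c(6, 7, 10, 15, 8, 12, 20))
  grp <- tibble::tibble(sample_id = cl$sample_id,
                        group = rep(c("high", "low"), c(4, 3)))
  cmp <- km_logrank(grp, cl, "os")
  expect_equal(cmp$chisq,
               logrank_oracle(cl$os_time, cl$os_event, grp$group),
               tolerance = 1e-10)
  # identical groups: statistic 0, p = 1
  cl2 <- tibble::tibble(sample_id = paste0("s", 1:6),
                        os_event = rep(c(1L, 0L), 3),
                        os_time = rep(c(2, 5), 3))
  grp2 <- tibble::tibble(sample_id = cl2$sample_id,
                         group = rep(c("high", "low"), each = 3))
  # arms hold identical event/censor patterns
  cl2$os_time <- c(2, 5, 8, 2, 5, 8); cl2$os_event <- c(1L, 1L, 0L, 1L, 1L, 0L)
  cmp2 <- km_logrank(grp2, cl2, "os")
  expect_equal(cmp2$chisq, 0, tolerance = 1e-10)
  expect_equal(cmp2$p_value, 1)
  expect_error(km_logrank(grp2[1:3, ], cl2, "os"), "non-empty")
})

test_that("KM curves equal the direct product-limit oracle", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    cl <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                         os_event = rbinom(n, 1, 0.7),
                         os_time = round(rexp(n, 0.2), 1) + 0.1)
    grp <- tibble::tibble(sample_id = cl$sample_id,
                          group = rep(c("high", "low"), length.out = n))
    cmp <- km_logrank(grp, cl, "os")
    for (g in c("high", "low")) {
      idx <- grp$group == g
      orc <- km_oracle(cl$os_time[idx], cl$os_event[idx])
      got <- tidy(cmp) |> dplyr::filter(group == g, n_event > 0)
      expect_equal(got$survival[match(orc$time, got$time)], orc$survival,
                   tolerance = 1e-10)
    }
  }
})

test_that("log-rank is invariant to group relabelling and permutation p works", {
  set.seed(24)
  cl <- tibble::tibble(sample_id = sprintf("s%02d", 1:16),
                       os_event = rbinom(16, 1, 0.8),
                       os_time = rexp(16, 0.3))
  grp <- tibble::tibble(sample_id = cl$sample_id,
                        group = rep(c("high", "low"), 8))
  a <- km_logrank(grp, cl, "os")
  swapped <- grp |> dplyr::mutate(group = ifelse(group == "high", "low", "high"))
  b <- km_logrank(swapped, cl, "os")
  expect_equal(a$chisq, b$chisq, tolerance = 1e-12)
  p <- km_logrank(grp, cl, "os", method = "permutation", n_perm = 200, seed = 2)
  expect_true(p$p_value > 0 && p$p_value <= 1)
  expect_equal(p$method, "permutation")
})

test_that("stage enrichment reproduces contingency structure and edge cases", {
  sc <- tibble::tibble(sample_id = sprintf("s%03d", 1:20),
                       score = 1:20,
                       group = factor(rep(c("high", "low"), 10),
                                      levels = c("high", "low")))
  cl <- tibble::tibble(sample_id = sc$sample_id,
                       stage = rep(c("II", "III"), each = 10))
  res <- stage_enrichment(sc, cl)
  expect_equal(sum(res$table), 20)
  expect_equal(res$p_value, fisher_enum_2x2(unclass(res$table)),
               tolerance = 1e-10)
  # identical stage mix in both score groups: no association
  cl2 <- tibble::tibble(sample_id = sc$sample_id,
                        stage = rep(c("I", "I", "IV", "IV"), 5))
  expect_equal(stage_enrichment(sc, cl2)$p_value, 1)
  # zero margin: warn, p = 1; unknown stages counted
  cl3 <- tibble::tibble(sample_id = sc$sample_id,
                        stage = c(rep("II", 18), NA, NA))
  expect_warning(res3 <- stage_enrichment(sc, cl3), "margin")
  expect_equal(res3$p_value, 1)
  expect_equal(res3$n_unknown, 2)
})

test_that("stratified analyses filter, compare and skip as specified", {
  co <- simulate_cohort(sim_config(n_samples = 240, n_genes = 60,
                                   n_prognostic = 6, effect_size = 1.2,
                                   seed = 25))
  sig <- mk_sig(co$truth$gene, 0.5 * co$truth$sign)
  sc <- score_cohort(co$expression, sig)
  spec <- list(
    list(name = "dss_all", endpoint = "dss"),
    list(name = "os_all", endpoint = "os"),
    list(name = "dfs_stage2", endpoint = "dfs", filter = list(stage = "II")),
    list(name = "dfs_stage23", endpoint = "dfs", filter = list(stage = c("II", "III"))),
    list(name = "os_pmmr_act3", endpoint = "os",
         filter = list(stage = "III", mmr_status = "pMMR", act_flag = TRUE)),
    list(name = "rfs_pmmr", endpoint = "rfs", filter = list(mmr_status = "pMMR")),
    list(name = "act_in_low", endpoint = "os", compare = "act", within = "low",
         filter = list(stage = c("II", "III"), mmr_status = "pMMR")),
    list(name = "act_in_high", endpoint = "os", compare = "act", within = "high",
         filter = list(stage = c("II", "III"), mmr_status = "pMMR")),
    list(name = "empty", endpoint = "os", filter = list(stage = "V"))
  )
  out <- stratified_analysis(sc, co$clinical, spec)
  expect_equal(nrow(out), 9)
  expect_true(out$skipped[out$analysis == "empty"])
  expect_match(out$reason[out$analysis == "empty"], "no samples")
  done <- out |> dplyr::filter(!skipped)
  expect_true(all(done$p_value >= 0 & done$p_value <= 1))
  expect_match(out$filter[out$analysis == "dfs_stage23"], "stage=II\\|III")
})

test_that("a planted treatment interaction is recovered in the right arm", {
  ps <- sapply(1:12, function(s) {
    co <- simulate_cohort(sim_config(n_samples = 400, n_genes = 30,
                                     n_prognostic = 6, effect_size = 0.8,
                                     act_effect_lowrisk = -1.2,
                                     act_effect_highrisk = 0,
                                     baseline_hazard = 0.25, seed = 500 + s))
    sig <- mk_sig(co$truth$gene, 0.5 * co$truth$sign)
    sc <- score_cohort(co$expression, sig)
    out <- stratified_analysis(sc, co$clinical, list(
      list(name = "low", compare = "act", within = "low", endpoint = "rfs"),
      list(name = "high", compare = "act", within = "high", endpoint = "rfs")))
    out$p_value
  })
  # benefit planted only among low-risk patients: detected there far more often
  expect_gt(mean(ps[1, ] < 0.05), 0.5)
  expect_gt(mean(ps[1, ] < 0.05), mean(ps[2, ] < 0.05))
})
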