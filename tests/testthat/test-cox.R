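test_that("housekeeping normalisation divides by the geometric mean", {
  x <- matrix(c(8, 2, 4, 8,
                16, 1, 1, 1), ncol = 2,
              dimnames = list(c("gX", "TFRC", "GUSB", "RPLP0"), c("s1", "s2")))
  norm <- housekeeping_normalize(x, pseudocount = 0)
  expect_equal(norm["gX", "s1"], 8 / 4)   # geomean(2,4,8) = 4
  expect_equal(norm["gX", "s2"], 16)      # housekeeping all 1: unchanged
  expect_equal(unname(attr(norm, "size_factors")), c(4, 1))
  expect_true(all(c("TFRC", "GUSB", "RPLP0") %in% rownames(norm)))
})

test_that("pseudocount policy enters the geometric mean as stated", {
  x <- matrix(c(5, 0, 1, 1), ncol = 1,
              dimnames = list(c("gX", "TFRC", "GUSB", "RPLP0"), "s1"))
  norm <- housekeeping_normalize(x, pseudocount = 0.01)
  expect_equal(unname(attr(norm, "size_factors")),
               exp(mean(log(c(0.01, 1.01, 1.01)))))
  x0 <- x; x0[2:4, 1] <- 0
  expect_error(housekeeping_normalize(x0), "zero in sample")
  expect_error(housekeeping_normalize(x[1, , drop = FALSE]), "none of the housekeeping")
})

test_that("normalisation cancels per-sample positive rescaling", {
  co <- simulate_cohort(sim_config(n_samples = 30, n_genes = 60,
                                   n_prognostic = 5, seed = 14))
  x <- co$expression
  f <- runif(ncol(x), 0.2, 5)
  # the exact invariance holds without the pseudocount (values are positive)
  n1 <- housekeeping_normalize(x, pseudocount = 0)
  n2 <- housekeeping_normalize(sweep(x, 2, f, "*"), pseudocount = 0)
  expect_equal(unclass(n1)[, ], unclass(n2)[, ], tolerance = 1e-9)
})

test_that("univariate ranking orders by p, flags degenerate genes last", {
  co <- simulate_cohort(sim_config(n_samples = 120, n_genes = 60,
                                   n_prognostic = 6, effect_size = 1.2, seed = 15))
  x <- co$expression
  x <- rbind(x, flat = rep(3, ncol(x)),
             dup = 2 * x[co$truth$gene[1], ] )  # proportional duplicate
  rk <- univariate_rank(x, co$clinical, endpoint = "dfs")
  expect_equal(rk$status[rk$gene == "flat"], "constant")
  expect_equal(rk$gene[nrow(rk)], "flat")
  # a gene exactly proportional to another has identical p; tie broken
  # deterministically by |coef| then identifier
  p_dup <- rk$p_value[rk$gene == "dup"]
  p_orig <- rk$p_value[rk$gene == co$truth$gene[1]]
  expect_equal(p_dup, p_orig, tolerance = 1e-8)
  expect_true(all(diff(rk$p_value[rk$status == "ok"]) >= -1e-12))
  # no events is an error
  cl0 <- co$clinical
  cl0$dfs_event <- 0L
  expect_error(univariate_rank(x, cl0), "no events")
})

test_that("univariate Cox recovers a known log hazard ratio", {
  beta <- 0.7
  est <- sapply(1:60, function(s) {
    set.seed(s)
    x <- rnorm(500)
    t <- rexp(500, rate = 0.2 * exp(beta * x))
    unname(coef(survival::coxph(survival::Surv(t, rep(1, 500)) ~ x)))
  })
  expect_lt(abs(mean(est) - beta) / beta, 0.1)
})

test_that("forward selection base case and trace shape", {
  co <- simulate_cohort(sim_config(n_samples = 160, n_genes = 80,
                                   n_prognostic = 8, effect_size = 1.2, seed = 16))
  norm <- housekeeping_normalize(co$expression)
  ids <- co$clinical$sample_id
  train <- ids[1:80]; test <- ids[81:160]
  rk <- univariate_rank(norm[, train], co$clinical, "dfs")
  sig1 <- forward_cox_select(norm, co$clinical, train, test, rk, max_k = 1)
  expect_equal(nrow(sig1$genes), 1)
  expect_equal(sig1$genes$gene, rk$gene[1])
  # with a single covariate the multivariate fit IS the univariate fit
  expect_equal(sig1$genes$beta, rk$coef[1], tolerance = 1e-8)
  sig <- forward_cox_select(norm, co$clinical, train, test, rk, max_k = 10)
  expect_equal(nrow(sig$trace), 10)
  expect_equal(sig$trace$k, 1:10)
  expect_equal(sig$km_p, min(sig$trace$km_p, na.rm = TRUE))
  expect_equal(sig$k_selected,
               min(sig$trace$k[which(sig$trace$km_p == sig$km_p)]))
  expect_warning(forward_cox_select(norm, co$clinical, train, test,
                                    rk[1:3, ], max_k = 10), "truncated")
})

test_that("signature serialisation round-trips risk scores exactly", {
  co <- simulate_cohort(sim_config(n_samples = 100, n_genes = 60,
                                   n_prognostic = 6, effect_size = 1, seed = 18))
  norm <- housekeeping_normalize(co$expression)
  ids <- co$clinical$sample_id
  rk <- univariate_rank(norm[, ids[1:50]], co$clinical, "dfs")
  sig <- forward_cox_select(norm, co$clinical, ids[1:50], ids[51:100], rk,
                            max_k = 6)
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_signature(sig, path)
  sig2 <- read_signature(path)
  expect_identical(sig2$genes$beta, sig$genes$beta)
  expect_identical(sig2$genes$gene, sig$genes$gene)
  expect_identical(sig2$housekeeping, sig$housekeeping)
  s1 <- score_cohort(co$expression, sig)
  s2 <- score_cohort(co$expression, sig2)
  expect_identical(s1$score, s2$score)
})

test_that("the log2 option propagates from fitting through scoring", {
  co <- simulate_cohort(sim_config(n_samples = 100, n_genes = 60,
                                   n_prognostic = 6, effect_size = 1, seed = 20))
  norm <- housekeeping_normalize(co$expression)
  ids <- co$clinical$sample_id
  rk <- univariate_rank(norm[, ids[1:50]], co$clinical, "dfs", log2 = TRUE)
  sig <- forward_cox_select(norm, co$clinical, ids[1:50], ids[51:100], rk,
                            max_k = 5, log2 = TRUE)
  expect_true(sig$log2)
  sc <- score_cohort(co$expression, sig)
  e <- log2(housekeeping_normalize(co$expression)[sig$genes$gene, , drop = FALSE] + 1)
  expect_equal(sc$score, as.vector(crossprod(e, sig$genes$beta)))
  # the flag survives serialisation
  path <- tempfile(); on.exit(unlink(path))
  write_signature(sig, path)
  expect_true(read_signature(path)$log2)
  # screening on the log scale matches a direct transform
  lab <- assign_prognosis_labels(co$clinical)
  r_log <- gene_prognosis_correlation(co$expression, lab, log2 = TRUE)
  r_man <- gene_prognosis_correlation(log2(co$expression + 1), lab)
  expect_equal(r_log$r, r_man$r)
})

test_that("risk-score ordering is invariant to per-sample rescaling", {
  co <- simulate_cohort(sim_config(n_samples = 80, n_genes = 60,
                                   n_prognostic = 6, effect_size = 1, seed = 19))
  norm <- housekeeping_normalize(co$expression)
  ids <- co$clinical$sample_id
  rk <- univariate_rank(norm[, ids[1:40]], co$clinical, "dfs")
  sig <- forward_cox_select(norm, co$clinical, ids[1:40], ids[41:80], rk,
                            max_k = 5)
  sig$pseudocount <- 0  # exact invariance needs no zero-protection here
  f <- runif(ncol(co$expression), 0.5, 2)
  s1 <- score_cohort(co$expression, sig)
  s2 <- score_cohort(sweep(co$expression, 2, f, "*"), sig)
  expect_equal(order(s1$score), order(s2$score))
  expect_identical(s1$group, s2$group)
})
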