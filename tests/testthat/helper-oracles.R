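# Independent oracles used to cross-check the implementation.

# sample() one element safely even from length-1 vectors
pick1 <- function(x) x[sample.int(length(x), 1)]

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration on a
# 2x2 table (margins fixed): sum of probabilities of all tables whose point
# probability is <= that of the observed table.
fisher_enum_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson correlation from the raw definition.
pearson_direct <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Brute-force correlation screen: per-gene loop, then filter and sort.
screen_bruteforce <- function(expr, y, threshold) {
  r <- apply(expr, 1L, function(g) {
    if (sd(g) == 0) 0 else pearson_direct(g, y)
  })
  keep <- names(r)[abs(r) >= threshold]
  keep[order(-abs(r[keep]), keep)]
}

# AUC as the Mann-Whitney pair-counting statistic (ties count 1/2).
auc_paircount <- function(score_pos, score_neg) {
  cmp <- outer(score_pos, score_neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Product-limit survival curve by direct evaluation: S(t) over distinct
# event times.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# Two-group log-rank chi-squared from the observed-minus-expected table.
logrank_oracle <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# A small deterministic two-class expression fixture: the first
# `n_signal` genes separate poor from good cleanly, half up- and half
# down-regulated (so class centroids vary across the gene axis, as a real
# signature's do).
make_separable <- function(n_poor = 8, n_good = 12, n_signal = 10,
                           n_noise = 20, sep = 2, noise = 0.1, seed = 42) {
  set.seed(seed)
  n <- n_poor + n_good
  ids <- sprintf("s%02d", seq_len(n))
  genes <- sprintf("g%03d", seq_len(n_signal + n_noise))
  x <- matrix(rnorm((n_signal + n_noise) * n, sd = noise),
              nrow = n_signal + n_noise, dimnames = list(genes, ids))
  signs <- rep_len(c(1, -1), n_signal)
  x[seq_len(n_signal), seq_len(n_poor)] <-
    x[seq_len(n_signal), seq_len(n_poor)] + signs * sep
  labels <- tibble::tibble(
    sample_id = ids,
    label = factor(rep(c("poor", "good"), c(n_poor, n_good)),
                   levels = c("poor", "good", "excluded"))
  )
  list(expr = x, labels = labels, signal_genes = genes[seq_len(n_signal)])
}
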