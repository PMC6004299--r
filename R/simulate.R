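#' Simulation settings for a synthetic prognosis cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator.  The
#' defaults describe the study conditions the pipeline was designed around: a
#' colon-adenocarcinoma-sized cohort (240 patients), RPKM-like RNA-seq
#' expression on a log-normal scale, a planted block of prognostic genes that
#' load on a common latent risk factor, three stable housekeeping genes
#' (TFRC, GUSB, RPLP0), exponential relapse/death times with independent
#' censoring, and stage/MMR/adjuvant-chemotherapy covariates whose
#' distribution tracks true risk.
#'
#' @param n_samples Number of patients.
#' @param n_genes Total number of gene rows, including housekeeping genes.
#' @param n_prognostic Number of planted prognostic genes (must fit inside
#'   the non-housekeeping genes).
#' @param effect_size Log hazard ratio per unit of the latent risk factor.
#'   `0` plants no signal.
#' @param baseline_hazard Relapse hazard (events per year) at average risk.
#' @param censor_rate Hazard of independent exponential censoring (per year);
#'   `0` disables random censoring.
#' @param followup_horizon Administrative censoring time in years; `Inf`
#'   disables it.
#' @param housekeeping_genes Identifiers of the stable reference genes.
#' @param noise_sd Per-gene standard deviation of log expression.
#'   Housekeeping genes use a quarter of this, keeping their coefficient of
#'   variation below `noise_sd / 2`.
#' @param latent_loading Correlation of each planted gene's (signed) z-scored
#'   log expression with the latent risk factor.
#' @param background_death_rate Hazard of death from other causes (per year).
#' @param mean_death_gap Mean years from relapse to disease death.
#' @param stage_assoc Slope of the latent risk factor in the cumulative-logit
#'   model assigning tumour stage, so stage-score enrichment is recoverable.
#' @param pmmr_rate Probability of a proficient mismatch-repair (pMMR) tumour.
#' @param act_effect_lowrisk,act_effect_highrisk Log hazard ratio of adjuvant
#'   chemotherapy on relapse among below-/above-average latent-risk patients;
#'   both `0` by default (no treatment interaction planted).
#' @param seed Integer seed; the same configuration always yields a
#'   bit-identical cohort.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples = 240,
                       n_genes = 1000,
                       n_prognostic = 20,
                       effect_size = 1.0,
                       baseline_hazard = 0.12,
                       censor_rate = 0.05,
                       followup_horizon = 10,
                       housekeeping_genes = c("TFRC", "GUSB", "RPLP0"),
                       noise_sd = 0.6,
                       latent_loading = 0.7,
                       background_death_rate = 0.02,
                       mean_death_gap = 1.5,
                       stage_assoc = 0.8,
                       pmmr_rate = 0.85,
                       act_effect_lowrisk = 0,
                       act_effect_highrisk = 0,
                       seed = 1L) {
  if (!is_count(n_samples) || !is_count(n_genes)) {
    abort("`n_samples` and `n_genes` must be positive integers.")
  }
  if (!is.numeric(n_prognostic) || n_prognostic < 0 ||
      n_prognostic > n_genes - length(housekeeping_genes)) {
    abort("`n_prognostic` must fit inside the non-housekeeping genes.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (latent_loading < 0 || latent_loading > 1) {
    abort("`latent_loading` must be in [0, 1].")
  }
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be positive.")
  if (censor_rate < 0 || background_death_rate < 0) {
    abort("hazard rates must be non-negative.")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_genes = as.integer(n_genes),
         n_prognostic = as.integer(n_prognostic),
         effect_size = effect_size,
         baseline_hazard = baseline_hazard,
         censor_rate = censor_rate,
         followup_horizon = followup_horizon,
         housekeeping_genes = housekeeping_genes,
         noise_sd = noise_sd,
         latent_loading = latent_loading,
         background_death_rate = background_death_rate,
         mean_death_gap = mean_death_gap,
         stage_assoc = stage_assoc,
         pmmr_rate = pmmr_rate,
         act_effect_lowrisk = act_effect_lowrisk,
         act_effect_highrisk = act_effect_highrisk,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# exponential draws that tolerate rate 0 (-> never happens)
rexp0 <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else rexp(n, rate = rate)
}

#' Generate a synthetic cohort with planted prognostic genes
#'
#' Draws an RPKM-like expression matrix and a clinical table with four
#' survival endpoints (OS, DSS, DFS, RFS) from a single latent-risk model.
#' Each patient carries a latent risk factor \eqn{u \sim N(0,1)}; planted
#' prognostic genes load on \eqn{u} (with alternating signs), the relapse
#' hazard is \eqn{h_0 \exp(\beta u)} with \eqn{\beta} = `effect_size`, death
#' from disease follows relapse after an exponential gap, and death from
#' other causes, random censoring and an administrative horizon compete.
#' Tumour stage is assigned by a cumulative-logit model increasing in
#' \eqn{u}, so stage enrichment in high-score groups is recoverable
#' downstream.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` list with elements
#'   * `expression`: genes x samples matrix of positive RPKM-like values;
#'   * `clinical`: tibble with `sample_id`, `age`, `sex`, the
#'     `{os,dss,dfs,rfs}_{event,time}` columns (times in years), `stage`
#'     (`"I"`..`"IV"`), `mmr_status` (`"pMMR"`/`"dMMR"`), `act_flag`
#'     (logical), and the hidden `latent_risk`;
#'   * `truth`: tibble of planted genes with their sign and effect size;
#'   * `config`: the configuration used.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 60, n_genes = 100, seed = 7))
#' dim(cohort$expression)
#' cohort$truth
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_samples
  hk <- config$housekeeping_genes
  n_hk <- length(hk)
  n_free <- config$n_genes - n_hk
  genes <- c(sprintf("G%05d", seq_len(n_free)), hk)
  samples <- sprintf("S%04d", seq_len(n))
  prognostic <- genes[seq_len(config$n_prognostic)]
  signs <- rep_len(c(1, -1), config$n_prognostic)

  # latent per-sample risk and gene-level baselines
  u <- rnorm(n)
  mu <- c(rnorm(n_free, mean = 3, sd = 1.5), rnorm(n_hk, mean = log(300), sd = 0.3))

  # z-scored log-expression: planted genes share the latent factor
  lambda <- config$latent_loading
  z <- matrix(rnorm(config$n_genes * n), nrow = config$n_genes,
              dimnames = list(genes, samples))
  if (config$n_prognostic > 0) {
    idx <- seq_len(config$n_prognostic)
    z[idx, ] <- signs * (lambda * rep(u, each = config$n_prognostic) +
                           sqrt(1 - lambda^2) * z[idx, , drop = FALSE])
  }
  sds <- c(rep(config$noise_sd, n_free), rep(config$noise_sd / 4, n_hk))
  expr <- exp(mu + sds * z)

  # covariates (stage probability increases with true risk)
  theta <- stats::qlogis(c(0.17, 0.57, 0.88))
  cum <- stats::plogis(outer(theta, config$stage_assoc * u, "-"))
  ustage <- runif(n)
  stage <- c("I", "II", "III", "IV")[1L + colSums(rbind(cum) < rep(ustage, each = 3))]
  mmr <- ifelse(runif(n) < config$pmmr_rate, "pMMR", "dMMR")
  act <- runif(n) < ifelse(stage %in% c("III", "IV"), 0.7, 0.25)

  # event machinery
  act_lp <- ifelse(act, ifelse(u < 0, config$act_effect_lowrisk,
                               config$act_effect_highrisk), 0)
  relapse_hazard <- config$baseline_hazard * exp(config$effect_size * u + act_lp)
  t_relapse <- rexp(n) / relapse_hazard
  t_dd <- t_relapse + rexp0(n, 1 / config$mean_death_gap)
  t_oc <- rexp0(n, config$background_death_rate)
  cens <- pmin(rexp0(n, config$censor_rate), config$followup_horizon)

  obs <- function(t_event) {
    t_obs <- pmin(t_event, cens)
    list(time = t_obs, event = as.integer(t_event <= cens))
  }
  rfs <- obs(pmin(t_relapse, t_oc))
  rfs$event <- as.integer(rfs$event == 1L & t_relapse <= t_oc)
  dfs <- obs(pmin(t_relapse, t_oc))
  t_death <- pmin(t_dd, t_oc)
  os <- obs(t_death)
  dss <- obs(t_death)
  dss$event <- as.integer(dss$event == 1L & t_dd <= t_oc)

  clinical <- tibble(
    sample_id = samples,
    age = round(pmin(pmax(rnorm(n, 65, 12), 30), 90), 1),
    sex = ifelse(runif(n) < 0.5, "male", "female"),
    os_event = os$event, os_time = os$time,
    dss_event = dss$event, dss_time = dss$time,
    dfs_event = dfs$event, dfs_time = dfs$time,
    rfs_event = rfs$event, rfs_time = rfs$time,
    stage = stage, mmr_status = mmr, act_flag = act,
    latent_risk = u
  )

  structure(
    list(expression = expr,
         clinical = clinical,
         truth = tibble(gene = prognostic, sign = signs,
                        effect = config$effect_size),
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d samples, %d planted prognostic genes (effect %.2f), seed %d\n",
              nrow(x$expression), ncol(x$expression), nrow(x$truth),
              x$config$effect_size, x$config$seed))
  invisible(x)
}

#' Expand genes into microarray-style probes
#'
#' Produces a probe-level matrix with `n_probes` probes per gene plus the
#' probe-to-gene map, for exercising probe collapsing.  Probes jitter the
#' gene's values multiplicatively; with `decoy = TRUE` every probe after the
#' first is a within-gene permutation across samples, i.e. a probe with the
#' right scale but no association with outcome.
#'
#' @param expr Genes x samples expression matrix.
#' @param genes Genes to expand (default: all rows).
#' @param n_probes Probes per gene.
#' @param probe_noise_sd Log-scale jitter SD applied per probe.
#' @param decoy Make probes 2..n pure-noise permutations.
#' @param seed Integer seed.
#' @return List with `probes` (probe x sample matrix) and `map`
#'   (tibble `probe_id`, `gene`).
#' @export
make_probe_matrix <- function(expr, genes = NULL, n_probes = 2,
                              probe_noise_sd = 0.2, decoy = FALSE, seed = 1L) {
  check_expression(expr)
  genes <- genes %||% rownames(expr)
  set.seed(seed)
  rows <- purrr::map(genes, function(g) {
    base <- expr[g, ]
    purrr::map(seq_len(n_probes), function(k) {
      v <- base * exp(rnorm(length(base), 0, probe_noise_sd))
      if (decoy && k > 1L) v <- sample(v)
      v
    })
  })
  probes <- do.call(rbind, purrr::flatten(rows))
  map <- tibble(
    probe_id = as.vector(t(outer(genes, seq_len(n_probes),
                                 function(g, k) sprintf("%s_p%d", g, k)))),
    gene = rep(genes, each = n_probes)
  )
  rownames(probes) <- map$probe_id
  colnames(probes) <- colnames(expr)
  list(probes = probes, map = map)
}
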