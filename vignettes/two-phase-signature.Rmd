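---
title: "Two-phase discovery of weighted prognosis signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase discovery of weighted prognosis signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsig)
```

This vignette is the package's account of the science it implements: the
statistical model behind each stage, the parameters that matter and their
defaults, what the synthetic-cohort generator does and does not emulate,
and the choices we made where the design was genuinely open.

## The problem

Tumour-stage systems leave large outcome heterogeneity unexplained:
patients at the same stage relapse at very different rates and differ in
benefit from adjuvant chemotherapy. A *prognosis signature* is a small set
of genes whose (weighted) expression separates patients into high- and
low-risk groups with different survival. `progsig` implements a two-phase
supervised pipeline for building such signatures from a gene × sample
expression matrix and per-patient outcome annotations, plus the validation
battery used to test one on independent cohorts.

## Phase I: correlation screen and centroid classifier

**Grouping.** With dichotomisation horizon $h$ (default 3 years),
a patient is *poor* prognosis if relapse occurred before $h$, *good* if
relapse-free follow-up reaches $h$, and *excluded* otherwise — a
relapse-free patient censored before $h$ carries no information about
3-year status, so exclusion is the only honest assignment
(`assign_prognosis_labels()`). Times are in years; a `time_unit = "days"`
argument converts at 365.25 days/year.

**Screen.** For every gene we compute the Pearson correlation $r_g$
between expression and the label coded poor = 1, good = 0
(`gene_prognosis_correlation()`). Against a binary vector this is the
point-biserial correlation, and any affine recoding of the labels changes
only its sign — so the coding fixes a sign convention (positive $r$ means
higher expression in poor-prognosis patients) and nothing else. Genes with
$|r_g| \ge 0.3$ are retained and ranked by $|r|$ (`screen_genes()`); the
comparison is inclusive, ties break by gene identifier, and zero-variance
genes get $r = 0$ with a flag. Correlations use values as provided by
default; a `log2` switch (applying $\log_2(x+1)$) exists everywhere
expression enters a fit and propagates through the signature to scoring,
because RPKM-scale values are strongly right-skewed and the appropriate
scale is a user decision, not one we silently make.

**Permutation null.** How many genes would pass the screen by chance is
answered by permuting labels across samples `n_permutations` times and
recording the passing count per trial (`permutation_null()`). The
empirical p-value uses the add-one estimator
$p = (\#\{\text{trials} \ge \text{observed}\} + 1)/(B + 1)$, the standard
permutation-inclusive form that cannot return zero; at $B = 10{,}000$ with
18 exceedances it yields $19/10{,}001 \approx 0.0019$. Trials are
exchangeable and fully determined by the seed.

**Classifier.** For a gene set $S$, the class *templates* are the per-gene
means over good and poor training samples (`build_templates()`), and a
sample's risk coefficient is

$$\text{risk-coef} = \mathrm{cor}(x_S, \bar{x}^{good}_S) -
  \mathrm{cor}(x_S, \bar{x}^{poor}_S) \in [-2, 2],$$

low values indicating poor-prognosis-like profiles (`risk_coef()`).
Classification is by *rank cut*: all samples are ordered by risk-coef from
small to large and the first $n_{high}$ (the number of poor-prognosis
training patients) are called high genomic risk (`rank_cut_classify()`).
Expression is z-scored per gene before template correlation (mirroring the
centring/scaling applied before grouping); a raw-scale mode is available.
Note this classifier needs the template to *vary across genes*: a
signature whose genes all shift the same way yields a near-constant
centroid and an uninformative correlation, which is why real signatures
mix up- and down-regulated genes and our fixtures do too.

**LOOCV over nested sizes.** Candidate signatures are nested prefixes of
the ranking in steps of two (`candidate_sizes()`; 1510 ranked genes give
755 candidates). For each size and each left-out sample, templates are
rebuilt without it, risk-coefs computed for *all* samples — the left-out
sample participates in the ranking before the cut, exactly as the
procedure prescribes, which makes prediction depend on the cohort's score
distribution and we preserve that for fidelity — and an error is counted
when the left-out sample's genomic risk disagrees with its real risk
(`loocv_sweep()`). Error counts are *not* monotone in signature size in
general, so the package asserts only their range; the minimiser set is
reported and the selection rule among minimisers (`largest-min` by
default, `smallest-min` or `fixed:k` as alternatives) is exposed, since
"high accuracy towards the training samples" motivates the largest
minimiser without formalising a tie-break. Implementation note: for every
fold, correlations over *all* nested prefixes are obtained in one pass
from cumulative sums (each prefix's Pearson terms are running sums), so
the sweep is $O(\text{genes} \times \text{samples})$ per fold rather than
per size per fold.

**No-information-leak variant.** Because the screen itself sees all
training samples, `loocv_no_leak()` recomputes the screen inside every
fold, rebuilds that fold's signature, and predicts the left-out sample;
per-fold gene lists and their overlap with the full-data list quantify the
actual leak. Folds whose screen retains fewer than two genes fall back to
all genes, flagged.

**ROC comparison.** `roc_compare()` sweeps a threshold over the negated
risk-coef, integrates by trapezoid, and attaches the Hanley–McNeil
standard error and a normal-approximation 95% CI (the SE method is stated
because "SE" alone is not interpretable). Without score ties the trapezoid
AUC equals the Mann–Whitney pair-counting statistic, a property the tests
verify.

## Phase II: housekeeping normalisation and forward Cox selection

**Normalisation.** Each sample's column is divided by the geometric mean
of its housekeeping values — TFRC, GUSB, RPLP0 by default, reference genes
chosen for stability rather than involvement in energy metabolism or
cytoskeleton (`housekeeping_normalize()`). This makes profiles invariant
to per-sample scale (depth, array intensity) and portable across
platforms. Zeros would annihilate a geometric mean, so a pseudocount
(default 0.01, the scale of the smallest meaningful RPKM) is added to
housekeeping values first; a sample with all-zero housekeeping values is
an error, not a guess. The pseudocount slightly breaks *exact* scale
invariance (the tests verify exact invariance at pseudocount 0).

**Univariate ranking.** One proportional-hazards fit per gene (single
covariate, Efron tie handling — the better approximation and `survival`'s
default) orders genes by Wald p ascending; ties break by |coefficient|
then identifier, and degenerate or failed fits sink to the bottom with a
status flag (`univariate_rank()`).

**Forward selection.** Starting from the top-ranked gene, genes are added
one at a time to a multivariate Cox fit on the training split; at each
size $k$ the test split is scored with $\sum_i E_i \beta_i$, split at the
*test population's own* median — scores strictly below the median are low
risk, the rest high — and the two-group log-rank p recorded
(`forward_cox_select()`). The selected $k^*$ minimises this test-set KM-p,
smallest $k$ on ties (parsimony). Non-converging multivariate fits are
retried with a small ridge penalty (recorded); still-failing sizes are
skipped with status. Whether the split median should come from the test or
training population is not determined by the procedure's description; we
follow the validation rule's wording ("the median value of the
population" being evaluated) and expose `split_median = "train"` as the
alternative. The fitting endpoint defaults to disease-free survival, the
endpoint on which the discovery-cohort evaluation is framed; it is a
parameter, as is everything above (`pipeline_config()`).

**The signature object.** A `weighted_signature` carries the genes and
$\beta_i$, the normalisation rule (housekeeping set + pseudocount), the
endpoint, the optional log2 flag, and the selection trace; it serialises
to a small structured text file with coefficients at 17 significant
digits, so a save/load round-trip reproduces risk scores bit-exactly.

## Validation battery

`score_cohort()` applies the signature's own normalisation, computes
$\sum_i E_i \beta_i$, and median-splits (interpolated median; strictly
below → low; a degenerate all-equal score vector is flagged and falls to
the "rest are high" side of the rule). Missing signature genes are an
error — no silent imputation. For probe-level platforms,
`collapse_probes()` keeps, per gene, the probe with minimum univariate Cox
p (ties by probe identifier). `km_logrank()` produces product-limit curves
and the two-sample log-rank test; the default p-value is the $\chi^2_1$
approximation, with a permutation option for strata too small to trust it
(< 20 samples, say). `stratified_analysis()` expresses the standard
clinical questions — signature prognosis within stage II, II & III, pMMR,
ACT-treated subsets, and the treatment-interaction comparison of ACT vs
control *within* a score group — as a declarative list of filters;
unknown covariate values are excluded per analysis and empty arms are
skipped with recorded reasons. `stage_enrichment()` tests advanced-stage
(III & IV) enrichment in the high-score group by two-sided Fisher exact
test, the two-sided p being the sum of probabilities of all tables with
point probability at most the observed one — the convention that
reproduces the published worked examples to their printed precision.

## The synthetic-cohort generator

`simulate_cohort()` draws the statistical structure the pipeline assumes,
so every stage is testable without external downloads:

* **Latent risk.** Each patient carries $u \sim N(0,1)$. Planted
  prognostic genes load on $u$ with alternating signs (loading 0.7 on the
  z-scored log-expression scale); all other genes are independent noise.
  The relapse hazard is $h_0 e^{\beta u}$ with $\beta$ = `effect_size`.
  The loading construction keeps the defining property — planted gene
  expression shifts the hazard — while giving the planted set the
  correlated-block structure real prognostic programmes have, and keeps
  per-gene marginal effects detectable by univariate Cox at the stated
  study conditions.
* **Expression.** $\log$-normal RPKM-like values: per-gene baselines
  $\log$-normal around a median of ~20 RPKM, per-gene log-SD `noise_sd`
  (default 0.6). Housekeeping genes sit near 300 RPKM with a quarter of
  the noise, keeping their coefficient of variation under `noise_sd`/2.
* **Endpoints.** Exponential relapse times under the induced hazard —
  the minimal standard generative model for Cox recovery; death from
  disease follows relapse after an exponential gap (mean 1.5 y); death
  from other causes is an independent small hazard (0.02/y); censoring is
  independent exponential (0.05/y) plus an administrative horizon (10 y).
  RFS counts relapse, DFS relapse-or-death, OS any death, DSS disease
  death only — four correlated but distinct endpoint columns.
* **Covariates.** Stage I–IV from a cumulative-logit model increasing in
  $u$ (so stage-score enrichment is recoverable), pMMR at 85%, ACT more
  likely at stage III/IV, age and sex for balance testing. Optional
  parameters plant an ACT benefit only in low- (or high-) risk patients
  for interaction analyses.
* **Determinism.** One seed governs everything; identical configurations
  are bit-identical. A probe-duplication helper (`make_probe_matrix()`,
  with a decoy option producing association-free probes at the right
  scale) supports probe-collapsing tests.

Defaults (240 patients, 1000 genes, 20 planted prognostic genes, effect
size 1.0) mirror a mid-sized COAD discovery cohort at desk scale. What the
generator does **not** emulate: count noise and length biases of real
RNA-seq, batch effects, correlated noise beyond the planted block,
platform-specific probe behaviour beyond duplication, non-proportional
hazards, informative censoring, or missing clinical data. Passing tests
therefore demonstrate that the machinery is correct and recovers planted
truth under its stated assumptions — not that the signature discovered on
any real cohort is biologically right.

## Numerical choices and degenerate inputs

* Threshold comparisons are inclusive ($|r| \ge$ threshold); all
  tie-breaks are deterministic (gene/sample/probe identifier) so reruns
  are bit-identical.
* Zero-variance genes and profiles correlate as 0 by convention, flagged.
* The screen's empirical p uses the add-one estimator (never 0).
* Cox fits use Efron ties; multivariate failures retry with ridge 0.1.
* Medians are interpolated (even $n$: mean of central order statistics);
  "strictly below" sends exact-median samples to the high-risk side.
* File I/O round-trips doubles exactly: writing uses shortest-round-trip
  formatting (coefficients at 17 significant digits), reading uses the
  correctly rounded base-R parser.
* A single pipeline seed derives fixed per-stage sub-seeds, and the run
  manifest records an MD5 digest per output file, so rerun identity is
  checkable at the byte level.

## Problem sizes in the test-suite and acceptance script

The suites exercise the pipeline at desk scale, chosen to make stochastic
checks statistically meaningful while staying quick: oracle-equivalence
checks on matrices up to 100 × 20, cohorts up to 50 for the product-limit
oracle; parameter-recovery and power runs at 300 patients × 500 genes with
20 planted genes over 20 seeds; the type-I rate of the end-to-end pipeline
over 60 null replicates (a 20-draw binomial cannot distinguish a 5% method
from a 10% one); determinism on a 150 × 300 cohort. The acceptance script
reports each quantity with the problem size used.

## Known limitations

* The rank-cut classifier requires the left-out sample in the ranking, so
  Phase I predictions are cohort-relative by design; applying the
  centroid classifier to a single new sample needs a reference cohort.
* Forward selection explores only prefixes of the univariate ranking —
  deliberately, as the procedure it implements is plain forward addition,
  not penalised selection (no lasso/elastic-net).
* The signature adjusts for nothing: validation stratifies by stage/MMR/
  ACT but never fits stage-adjusted models.
* Very small strata make the $\chi^2$ log-rank approximation rough; use
  `method = "permutation"` there.
* The generator's planted truth is a single latent factor; methods could
  look better here than on real multi-programme tumours.
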