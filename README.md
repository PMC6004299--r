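# progsig

Discovery and validation of weighted gene-expression prognosis signatures
for solid tumours, built around the two-phase supervised machine-learning
design used for colon adenocarcinoma (COAD) cohorts: a correlation-screened
nearest-centroid classifier cross-validated over nested signature sizes
(Phase I), followed by forward Cox proportional-hazards selection of a
compact weighted signature whose risk score stratifies independent cohorts
by Kaplan–Meier/log-rank analysis (Phase II).

The intended users are computational biologists with a gene × sample
expression matrix (RPKM-like RNA-seq values or microarray probe
intensities) and per-patient outcome annotations (relapse/death indicators
and times, stage, mismatch-repair status, adjuvant-chemotherapy flags) who
want to derive — or apply — a prognostic score, with every stage testable
offline through a built-in synthetic-cohort generator.

## The method

**Grouping.** Patients relapsing within 3 years are *poor* prognosis,
patients relapse-free for at least 3 years are *good*; relapse-free
patients censored earlier are excluded (their 3-year status is unknowable).

**Phase I — centroid classifier.** Each gene is scored by the Pearson
correlation *r* between its expression and the binary prognosis label;
genes with |r| ≥ 0.3 are retained, ranked by |r|, and the retained-set size
is calibrated against a Monte-Carlo permutation null (the empirical
p-value uses the add-one estimator, e.g. 19/10,000 = 0.0019). For a
candidate signature the good- and poor-prognosis *templates* are the
per-gene class means, and each sample gets a risk coefficient

    risk-coef = cor(profile, good template) − cor(profile, poor template)

Samples are ranked by risk-coef from small to large and the first
*n*<sub>poor</sub> are called high genomic risk. Nested signatures (top 2,
4, 6, … ranked genes; 1510 genes give 755 candidates) are compared by
leave-one-out cross-validated error counts, with a stricter
no-information-leak variant that recomputes the screen inside every fold,
and by ROC curves (trapezoid AUC, Hanley–McNeil SE).

**Phase II — weighted Cox signature.** Expression is normalised per sample
by the geometric mean of the housekeeping genes TFRC, GUSB and RPLP0.
Genes are ranked by univariate Cox p-value on the training split, then
added one at a time to a multivariate Cox model; at each size the test
split is scored with

    Riskscore = Σᵢ Eᵢ · βᵢ

(*Eᵢ* normalised expression, *βᵢ* multivariate Cox coefficient), split at
the population median (scores strictly below the median are low risk), and
the two-group Kaplan–Meier log-rank p-value recorded. The size minimising
this test-set KM-p is the signature.

**Validation.** Any cohort — after probe-to-gene collapsing that keeps the
probe with minimum univariate Cox p — is scored, median-split, and compared
by KM/log-rank per endpoint (OS/DSS/DFS/RFS), within clinical strata
(stage, mismatch-repair status, adjuvant chemotherapy), and by Fisher
exact tests of advanced-stage enrichment in the high-score group.

## Worked example

```r
library(progsig)

cohort <- simulate_cohort(sim_config(n_samples = 150, n_genes = 300,
                                     n_prognostic = 20, effect_size = 1.0,
                                     seed = 8))
labels <- assign_prognosis_labels(cohort$clinical, horizon_years = 3)
attr(labels, "counts")
#>     poor     good excluded
#>       47       84       19

manifest <- run_full_pipeline(cohort$expression, cohort$clinical,
                              "signature_run",
                              pipeline_config(n_permutations = 2000,
                                              max_k = 20, seed = 1))
res <- attr(manifest, "results")
res$null
#> <perm_null> observed 7 genes at |r| >= 0.30; empirical p = 0.0009995 (2000 trials)
res$signature
#> <weighted_signature> 5 genes (endpoint DFS, test KM log-rank p = 0.000163)
#>   normalisation: geometric mean of TFRC, GUSB, RPLP0 (pseudocount 0.01)
res$validation$dfs
#> <survival_comparison> DFS: log-rank chisq = 14.478, p = 0.0001418 (chisq; n = high 75, low 75)
res$stage_enrichment
#> <contingency_result> Fisher exact (two-sided), p = 0.002883 (0 unknown excluded)
```

Reading the output: 7 of 300 genes pass the correlation screen on the
training split, far more than any of the 2000 label permutations
(empirical p ≈ 0.001, i.e. the screen is not a chance artefact). Forward
Cox selection settles on a 5-gene weighted signature whose risk score,
split at the cohort median, separates disease-free survival between the
high- and low-risk halves (log-rank p ≈ 1.4 × 10⁻⁴), and high-score
patients are enriched for stage III/IV tumours (Fisher p ≈ 0.003) — the
behaviour expected when the generator plants 20 prognostic genes at a log
hazard ratio of 1 per unit latent risk.

Result objects have `tidy()`/`glance()` methods and `autoplot()` figures
(LOOCV error profile, ROC curves, KM curves, permutation null); `run_full_pipeline()`
writes every stage's tables plus a manifest of MD5 digests, and reruns
with the same seed are byte-identical.

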