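---
title: "Evaluating missense pathogenicity predictors: concordance, performance, and circularity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating missense pathogenicity predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordkit)
```

## The problem

Clinical variant-interpretation guidelines (ACMG/AMP) admit computational
evidence — the PP3/BP4 codes — when "multiple lines" of in silico predictors
agree on a missense variant. In practice laboratories differ in how many and
which predictors they use, and the guideline never defines what concordance
buys you. concordkit provides the machinery to quantify that: it harmonizes
heterogeneous predictor outputs into comparable calls, enumerates every
combination of predictors and measures how often the combination is
unanimously right (*true concordance*), unanimously wrong (*false
concordance* — an error mode in which the in silico consensus opposes the
clinical assertion), or split; compares predictors as continuous classifiers
by ROC AUC with honest uncertainty; groups predictors into families that
tend to vote together; and builds the evaluation cohorts needed to keep
those comparisons honest against two kinds of benchmark circularity.

Everything runs equally on real inputs (ClinVar-style variant summaries plus
dbNSFP-style score tables) and on a synthetic generator with known ground
truth, so every stage is testable without external downloads.

## Harmonizing predictor outputs

Predictors disagree in *kind* before they disagree in content: some emit a
probability where higher means damaging (REVEL, VEST3), some a score where
lower means damaging (SIFT, FATHMM, PROVEAN), some categorical labels
(PolyPhen-2's benign/possibly/probably damaging, MutationTaster's A/D/N/P,
MutationAssessor's H/M/L/N, LRT's D/N/U). An `algorithm_spec` records, per
predictor, the output kind, the damaging direction, the decision threshold
or label map, and whether a publicly recommended threshold exists at all.
The shipped registry (`default_algorithm_registry()`,
`inst/extdata/algorithms.yaml`) covers 25 predictors, 18 of which carry a
public threshold and can be binarized; the 7 conservation-type scores
without one participate only in score-based analyses. Registry values are
deliberately user-editable — thresholds drift across predictor versions —
and the thresholds in force are logged into every analysis output.

Three rules do the harmonization work:

* **Multi-transcript cells** (`;`-separated in dbNSFP) collapse to the most
  damaging value — the minimum for lower-is-damaging predictors, the
  maximum otherwise (`most_damaging()`).
* **Binarization** is damaging-inclusive at the boundary: a score exactly at
  the threshold is called damaging (`binarize_score()`). The rule is
  arbitrary but deterministic, and it is applied consistently everywhere a
  cutoff is scanned, including `optimal_cutpoint()`.
* **Labels collapse** per the registry map; labels that mean "no call"
  (LRT's Unknown) and labels the map has never seen both become missing,
  the latter with a warning rather than an error, because label sets drift
  across dbNSFP releases (`map_categorical()`).

Missingness is explicit (`NA`) end to end — never a sentinel score — and
every analysis states its missing-data policy.

For score-based analyses, `rank_normalize()` aligns directions (negating
lower-is-damaging columns) and converts each column to fractional ranks in
(0, 1] with average ranks on ties. This is the same convention as dbNSFP
rankscores: scale-free, invariant under any strictly increasing transform
of a predictor's output, and it makes Euclidean distances between predictor
columns comparable. One consequence worth stating: a column of n tied
values gets rank (n+1)/(2n), not 0.5 exactly — for a constant column we
warn and apply the same rule rather than special-casing, since a constant
column carries no ranking information either way.

## Concordance and false concordance

Given a binary call matrix and ClinVar-style truth labels,
`combination_concordance()` classifies each variant, for a chosen predictor
combination, as truly concordant (unanimous call matching the assertion),
falsely concordant (unanimous call opposing it), or discordant. Two missing
-data policies are supported: `complete` (a variant counts only if every
member has a call) and `available` (at least two non-missing calls, with
unanimity judged over the non-missing members — unanimity of a single call
would be vacuous, so one call is not enough). `sweep_combinations()` runs
every size-k combination — 816, 3060, 8568 for k = 3, 4, 5 over 18
predictors — streaming so memory scales with the number of combinations,
not combinations × variants; `enumerate_combinations()` can exclude
subsets that co-list near-duplicate metapredictors (e.g. MetaSVM with
MetaLR). Pooled "all"-class rates are computed by pooling counts,
(true benign + true pathogenic) / (evaluable benign + evaluable
pathogenic), not by averaging the class-wise rates; this is the natural
reading and is documented so it can be changed.

`pairwise_agreement()` plus `pairwise_difference_test()` (Welch's unequal
-variance t-test, via `stats::t.test`) ask whether predictors agree less on
benign than pathogenic variants; `majority_opposition()` counts variants
whose truth label is opposed by at least a given fraction of the
non-missing calls. Reported percentages round half away from zero to one
decimal (`format_pct()`); raw counts and fractions are always retained.

```{r concordance-demo}
sim <- simulate_matrix(sim_config(n_benign = 300, n_pathogenic = 300,
                                  seed = 7))
specs <- lapply(stats::setNames(nm = colnames(sim$matrix$scores)), function(a)
  algorithm_spec(a, kind = "numeric", direction = "higher_damaging",
                 threshold = binormal_shift(0.8) / 2))
calls <- build_call_matrix(sim$matrix, specs)
combination_concordance(calls, c("alg1", "alg2", "alg3"),
                        truth_class = "benign", missing_policy = "complete")
```

## Performance: AUC, intervals, comparisons, cutpoints

`auc()` is the Mann–Whitney estimator with half-credit for ties, computed
via midranks. Direction comes from the spec, never from the data: an AUC
below 0.5 is reported as-is because silently flipping it would hide a
mis-specified direction in the registry.

`auc_ci()` offers two interval constructions. The default `delong` method
uses the DeLong variance of the placement values, but builds the normal
interval on the logit scale (delta method) and back-transforms: the
variance-stabilized form keeps the interval inside (0, 1) and is better
calibrated in moderate samples than the untransformed interval, to which it
falls back in degenerate cases (AUC of 0 or 1, zero variance). The
`bootstrap` method gives the percentile interval from stratified
within-class resampling with a required seed. The default level is 0.99.

`compare_auc()` tests the difference of two predictors' AUCs on the same
variants with a paired stratified bootstrap: each replicate resamples
variants within each truth class (every replicate keeps the original class
sizes), recomputes both AUCs, and the two-sided p-value comes from
z = observed difference / bootstrap SD. The default is 10,000 replicates;
examples here use fewer for speed. Pairwise-complete rows only.

`optimal_cutpoint()` scans every unique observed score as a
damaging-inclusive cutoff and maximizes the Youden index, breaking ties
toward higher specificity; PPV/NPV are computed at the sample prevalence.
Youden is the default because no single criterion is canonical; the
criterion is an explicit argument.

Missing data are handled complete-case *within* each predictor
(`auc_table()`), so each predictor is evaluated on the variants it actually
scored — per-predictor n varies and is reported alongside.

## Clustering predictors

Predictors borrow from each other (metapredictors ingest older predictors
as features) and from shared signals (conservation), so their scores
cluster. `ward_dendrogram()` clusters predictor columns of the
rank-normalized matrix (complete-case variants only, by default, to avoid
imputation artifacts) with Euclidean distance and Ward.D2 linkage.
`multiscale_bootstrap()` resamples variants at scale factors
r ∈ {0.5, …, 1.4} — resample size ⌈r·n⌉, with replacement — reclusters, and
records per original clade the proportion of resamples in which it
reappears (BP). `au_from_bp()` fits the signed-distance/curvature model
Φ⁻¹(1 − BP_r) = v·√r + c/√r by weighted least squares (binomial
delta-method weights) and reports the approximately unbiased support
AU = 1 − Φ(v − c). Clades whose BP is 1 (or 0) at every scale carry no
curvature information and get AU 1 (or 0) directly rather than a
meaningless fit. `stable_clusters()` returns the maximal non-root clades
with AU at or above the threshold (default 0.99).

The headline replicate budget of 50,000 is interpreted as the total across
scales — 5,000 per scale over 10 scales by default; both knobs are
configurable and examples below reduce them. Reproducibility is exact under
a fixed seed and config.

```{r cluster-demo}
alg <- data.frame(name = paste0("a", 1:6), target_auc = 0.8,
                  block = rep(1:3, each = 2))
sim2 <- simulate_matrix(sim_config(n_benign = 150, n_pathogenic = 150,
                                   algorithms = alg,
                                   block_correlation = 0.8, seed = 42))
dend <- cluster_predictors(rank_normalize(sim2$matrix),
                           cluster_config(n_boot_per_scale = 200, seed = 7))
stable_clusters(dend)
```

## Cohorts and circularity

`cohort` objects carry a key set plus a provenance string. The
constructions mirror the standard evaluation designs:

* **Review-status tiers** come from `filter_variants()` with `min_stars`
  (the review-star map follows standard ClinVar semantics: practice
  guideline 4, expert panel 3, multiple concordant submitters 2, single
  submitter 1 — conflicting interpretations also map to 1 star but drop
  out anyway because their collapsed class is neither benign nor
  pathogenic — and "no assertion criteria provided" 0).
* **Definite-only**: `exclude_likely` drops "Likely" assertions.
* **Date-difference sets** (`snapshot_diff()`) keep variants absent from an
  earlier release — variants deposited after a predictor's training cutoff
  cannot have been trained on (type 1 circularity control). Key match
  only; a reclassified variant is not "new".
* **Training-set exclusions** (`exclude_training()`) subtract explicit
  training keys.
* **Gene strata** (`stratify_genes()`): constraint bins on the ExAC
  missense Z score — [2.5, ∞), [0, 2.5), (−∞, 0); the printed edges "0–2.49"
  vs "> 2.5" leave (2.49, 2.5) unassigned, and these bins are the
  contiguous partition closest to them — plus inheritance-mode and
  oncogene/TSG strata from user-supplied gene lists (the lists are external
  resources; recomputing them is out of scope).
* **Balanced subset** (`balanced_subset()`): per gene, min(benign,
  pathogenic) variants of each class, sampled with a required seed — the
  type 2 circularity control.
* **Complete-case** (`complete_case()`): no missing call among the chosen
  predictors.

Type 2 circularity — a predictor exploiting the *class composition of the
gene* rather than variant-level signal — is made tangible by
`gene_composition_predictor()`: it scores a variant purely by the
(leave-one-out) pathogenic fraction of its gene. On a cohort where many
genes carry a single class this "predictor" looks excellent; on the
balanced subset of the same data it collapses. That contrast is the
qualitative signature by which real predictors (FATHMM being the known
example) are diagnosed.

```{r circularity-demo}
circ <- simulate_matrix(sim_config(n_benign = 500, n_pathogenic = 500,
                                   n_genes = 60, gene_imbalance = 0.9,
                                   seed = 37))$matrix
gc <- gene_composition_predictor(circ)
vars <- data.frame(key = rownames(circ$scores), gene_symbol = circ$gene,
                   clin_class = circ$truth)
bal <- subset_variants(circ, balanced_subset(vars, seed = 41))
c(unbalanced = auc(gc, circ$truth),
  balanced = auc(gene_composition_predictor(bal), bal$truth))
```

## The synthetic generator

`simulate_matrix()` draws scores from an equal-variance latent-factor
binormal model: for predictor a in correlation block g,

    s = sqrt(rho) * F_g + sqrt(1 - rho) * eps + mu_a * [pathogenic]

with F_g and eps standard normal, so every score has unit variance,
predictors within a block correlate at rho, and
mu_a = sqrt(2) * Φ⁻¹(target AUC) gives the target AUC exactly in
expectation (`binormal_shift()`). Defaults emulate the conditions the
pipeline is meant for: a few hundred variants per class, per-predictor
AUCs spanning the observed 0.5–0.96 range of published predictors,
within-family correlation, and 0–10% missingness. Variants are assigned to
genes with uniform or Zipf-like skewed sizes; `gene_imbalance` is the
probability a gene carries a single class.

What the generator deliberately does *not* model: structured missingness
(real dbNSFP missingness follows transcripts and genome builds, not
coin-flips — `apply_missingness()` is MCAR only), realistic marginal score
distributions of specific predictors, transcript-level effects, or
sequence context. Tests passing on synthetic data therefore validate the
*statistical machinery* — counting, enumeration, inference, clustering —
not any claim about a particular published predictor.

## Numerical choices and degenerate inputs

* Threshold boundary: damaging-inclusive everywhere.
* Ranks: average on ties; rank-normalization of a constant column warns.
* AU fit: BP values are clamped to [1/(B+1), B/(B+1)] before the probit;
  all-extreme BP vectors short-circuit to AU 0/1; fewer than two usable
  scales give NA with a flag.
* Bootstrap p-value with zero bootstrap SD: 1 when the observed delta is 0,
  else 0 (identical-score inputs).
* Welch test on two zero-variance but equal lists returns t = 0, p = 1;
  zero variance with unequal means is an explicit error.
* Percent formatting rounds half away from zero, one decimal, raw values
  retained.
* Every stochastic step (bootstraps, subsampling, simulation) takes an
  explicit seed; identical config + seed reproduces outputs byte-for-byte
  (`run_analysis()` writes a provenance JSON recording them).

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make Monte Carlo bounds tight while staying quick on a laptop:
concordance oracle equivalence on 200 random matrices up to 8 × 50;
AUC recovery at 2,000 + 2,000 variants; DeLong coverage over 1,000
simulated datasets of 200 + 200; clustering with 1,000 replicates per scale
on 9 predictors × 300 variants; circularity on 1,000 + 1,000 variants over
100 genes. Statistical checks use 3-standard-error bounds (Hanley–McNeil
for AUC, binomial elsewhere) rather than loose absolute tolerances.

## Known limitations

* ClinVar ingestion is tab-delimited only (no XML), one assembly at a
  time, no liftover; missense detection prefers a molecular-consequence
  column and falls back to parsing HGVS p. notation, which misses
  annotation-free rows.
* The registry's default thresholds are conventional, not authoritative;
  any serious analysis should pin them deliberately.
* `available`-policy concordance requires two calls; other minimums are
  not configurable.
* AU support is approximate by construction; with few variants or heavy
  ties the multiscale fit can be unstable at extreme BP values.
* The ">= 50% of predictors" opposition statistic counts non-missing calls
  only, so a variant scored by two predictors can be "majority-opposed" by
  a single call under the default fraction.
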