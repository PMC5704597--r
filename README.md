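# concordkit

Evaluation framework for in silico missense-variant pathogenicity
predictors.

Clinical variant classification under the ACMG/AMP guidelines admits
computational evidence (PP3/BP4) when multiple predictors agree — but in
practice labs use different predictors, different counts of them, and get
different answers. concordkit quantifies what predictor agreement is
actually worth:

* **Harmonization** — map 25 heterogeneous predictor outputs (numeric
  scores in either direction, categorical labels) to direction-aligned
  scores and binary damaging/tolerated calls via an editable per-algorithm
  registry (threshold, direction, label map), with explicit missingness
  and most-damaging-per-transcript reduction of dbNSFP-style cells.
* **Concordance** — for every combination of k predictors (all 816 / 3060 /
  8568 combinations of 3/4/5 out of 18), the fraction of variants where
  the combination is unanimously right (*true concordance*), unanimously
  wrong against the clinical assertion (*false concordance*), or split;
  pairwise agreement with Welch comparison across truth classes;
  majority-opposition counts.
* **Performance** — Mann–Whitney AUC (half-credit ties), 99% confidence
  intervals (variance-stabilized DeLong or stratified bootstrap), paired
  stratified-bootstrap AUC difference tests, Youden-optimal cutpoints with
  sensitivity/specificity/PPV/NPV.
* **Clustering** — Ward.D2 hierarchical clustering of predictors on
  rank-normalized scores with multiscale-bootstrap AU support; clades with
  AU ≥ 0.99 are called stable.
* **Cohorts** — review-star tiers, snapshot date-differences and
  training-set exclusions (type 1 circularity controls), gene-constraint /
  inheritance / oncogene-vs-TSG strata, per-gene class-balanced subsets
  (type 2 circularity control), complete-case restrictions.
* **Synthetic data** — a latent-factor binormal generator with exact
  target AUCs (`mu = sqrt(2) * qnorm(AUC)`), correlation blocks, MCAR
  missingness and tunable per-gene class imbalance, so the whole pipeline
  is testable with known ground truth; includes the gene-composition
  "predictor" that makes type 2 circularity visible.

The key statistics, for a combination C of predictors on variants with
truth labels:

    true concordance  = #{v : all calls in C equal and matching truth(v)} / #evaluable
    false concordance = #{v : all calls in C equal and opposing truth(v)} / #evaluable
    AUC = P(score_pathogenic > score_benign) + 1/2 P(equal)   (Mann–Whitney)
    AU(clade) = 1 - Phi(v - c),  from the WLS fit  Phi^-1(1 - BP_r) = v sqrt(r) + c / sqrt(r)

## Worked example

Five simulated predictors in three correlated families (two strong
metapredictors, two mid-range functional predictors, one weak conservation
score), 500 benign + 500 pathogenic variants, 5% missingness:

```r
library(concordkit)

alg <- data.frame(name = c("metaA", "metaB", "funcC", "funcD", "consE"),
                  target_auc = c(0.95, 0.93, 0.85, 0.80, 0.70),
                  block = c(1, 1, 2, 2, 3))
sim <- simulate_matrix(sim_config(n_benign = 500, n_pathogenic = 500,
                                  algorithms = alg, block_correlation = 0.7,
                                  missing_rate = 0.05, seed = 11))
m <- sim$matrix
specs <- lapply(stats::setNames(nm = alg$name), function(a)
  algorithm_spec(a, kind = "numeric", direction = "higher_damaging",
                 threshold = binormal_shift(alg$target_auc[alg$name == a]) / 2))
calls <- build_call_matrix(m, specs)

combination_concordance(calls, c("metaA", "funcC", "consE"),
                        truth_class = "benign", missing_policy = "complete")
#>         combination truth_class missing_policy n_evaluable n_true_concordant
#> 1 consE+funcC+metaA      benign       complete         426               200
#>   n_false_concordant n_discordant true_rate  false_rate
#> 1                  4          222 0.4694836 0.009389671
```

Of the 426 benign variants all three predictors scored, the trio is
unanimously correct on only 47% — and on 4 variants (0.9%) it is
unanimously *wrong*, the false-concordance error mode that would push a
benign variant toward a pathogenic interpretation. Requiring full
concordance leaves 222 variants (52%) with no usable in silico evidence.

```r
majority_opposition(calls, "benign", 0.5)
#> $count    [1] 74
#> $denominator [1] 500
#> $rate     [1] 0.148

auc_ci(m$scores[, "metaA"], m$truth, level = 0.99)
#> AUC 0.9524 (99% CI 0.9338-0.9660, delong; 475 pathogenic / 478 benign)

cmp <- compare_auc(m$scores[, "metaA"], m$scores[, "funcD"], m$truth,
                   n_boot = 2000, seed = 5)
#> delta AUC 0.135, bootstrap p 5e-19

dend <- cluster_predictors(rank_normalize(m, specs),
                           cluster_config(n_boot_per_scale = 500, seed = 3))
stable_clusters(dend)
#> [[1]] "funcC" "funcD"
#> [[2]] "metaA" "metaB"
```

14.8% of benign variants are called damaging by at least half of their
non-missing predictors; the strongest predictor's AUC (0.952) recovers its
generating target (0.95) with its 99% interval; the AUC gap to the weaker
predictor is significant by the paired stratified bootstrap; and the
bootstrap clustering recovers exactly the two planted multi-member
families as stable clades (AU ≥ 0.99).

Real data enter the same way via `read_clinvar_summary()` +
`filter_variants()` (inclusion filters, label collapsing, review stars)
and `read_score_table()` (dbNSFP-style tables keyed by
chr/pos/ref/alt), then flow through the identical analysis surface.
`run_analysis()` orchestrates declared multi-stage runs from a YAML/list
config and writes TSV tables plus a provenance JSON.

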