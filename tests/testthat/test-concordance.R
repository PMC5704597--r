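test_that("pairwise agreement counts only mutually non-missing calls", {
  # 10 variants, 2 with a missing value in alg2, 7 of the remaining 8 agree
  cm <- make_calls(c("D","D", "D","D", "D","D", "D","D", "T","T",
                     "T","T", "T","T", "D","T", "D",".", "T","."),
                   truth = rep("benign", 10), n_alg = 2)
  pa <- pairwise_agreement(cm, "all")
  expect_equal(pa$n_evaluable, 8L)
  expect_equal(pa$agreement, 7 / 8)

  identical_cols <- make_calls(rep(c("D","D"), 10), rep("pathogenic", 10), 2)
  expect_equal(pairwise_agreement(identical_cols, "all")$agreement, 1)
  complementary <- make_calls(rep(c("D","T"), 10), rep("pathogenic", 10), 2)
  expect_equal(pairwise_agreement(complementary, "all")$agreement, 0)
  # empty denominator flagged, not an error
  allmiss <- make_calls(rep(c(".", "."), 3), rep("benign", 3), 2)
  pa2 <- pairwise_agreement(allmiss, "all")
  expect_true(pa2$undefined)
  expect_true(is.na(pa2$agreement))
})

test_that("Welch comparison matches the textbook formula", {
  expect_equal(pairwise_difference_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$t, 0)
  same <- pairwise_difference_test(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  b <- c(0.2, 0.25, 0.3); p <- c(0.8, 0.85, 0.9)
  res <- pairwise_difference_test(b, p)
  # independent evaluation of Welch's statistic
  se <- sqrt(var(b) / 3 + var(p) / 3)
  t_hand <- (mean(b) - mean(p)) / se
  df_hand <- se^4 / ((var(b) / 3)^2 / 2 + (var(p) / 3)^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand))
  expect_error(pairwise_difference_test(c(0.1), c(0.2, 0.3)), "at least 2")
})

test_that("combination enumeration is lexicographic and honors exclusion pairs", {
  algs <- paste0("alg", sprintf("%02d", 1:18))
  expect_equal(ncol(enumerate_combinations(algs, 3)), 816L)
  expect_equal(ncol(enumerate_combinations(algs, 4)), 3060L)
  expect_equal(ncol(enumerate_combinations(algs, 5)), 8568L)
  expect_equal(ncol(enumerate_combinations(algs, 18)), 1L)
  expect_error(enumerate_combinations(algs, 0), "k must be")
  expect_error(enumerate_combinations(algs, 19), "k must be")
  # exclusion removes exactly the co-membership subsets: C(16, k-2) of them
  with_excl <- enumerate_combinations(algs, 3,
    exclusion_pairs = list(c("alg01", "alg02")))
  expect_equal(ncol(with_excl), 816L - choose(16, 1))
  expect_false(any(apply(with_excl, 2, function(cc)
    all(c("alg01", "alg02") %in% cc))))
  # deterministic lexicographic order
  ec <- enumerate_combinations(c("b", "a", "c"), 2)
  expect_equal(ec, matrix(c("a", "b", "a", "c", "b", "c"), nrow = 2))
})

test_that("combination concordance matches the spec's worked example", {
  # truth [B,B,P,P]; X calls [T,T,D,D]; Y calls [T,D,D,D]
  cm <- make_calls(c("T","T", "T","D", "D","D", "D","D"),
                   truth = c("benign", "benign", "pathogenic", "pathogenic"),
                   n_alg = 2)
  res <- combination_concordance(cm, c("alg1", "alg2"), "benign", "complete")
  expect_equal(res$n_evaluable, 2L)
  expect_equal(res$n_true_concordant, 1L)
  expect_equal(res$n_false_concordant, 0L)
  expect_equal(res$n_discordant, 1L)

  # single benign variant unanimously called damaging: false concordance 1.0
  cm2 <- make_calls(c("D","D"), "benign", 2)
  res2 <- combination_concordance(cm2, c("alg1", "alg2"), "benign", "complete")
  expect_equal(res2$false_rate, 1)
  expect_error(combination_concordance(cm2, character(0)), "empty")
  expect_error(combination_concordance(cm2, "nope"), "not in call matrix")
})

test_that("streaming engine equals the naive oracle on random matrices", {
  set.seed(20240117)
  for (rep in 1:200) {
    n_alg <- sample(2:8, 1)
    n_var <- sample(5:50, 1)
    cm <- random_call_matrix(n_var, n_alg, miss = runif(1, 0, 0.3))
    k <- sample(2:n_alg, 1)
    comb <- sample(colnames(cm$calls), k)
    for (policy in c("complete", "available")) {
      cls <- sample(c("all", "benign", "pathogenic"), 1)
      want <- naive_concordance(cm, comb, cls, policy)
      got <- combination_concordance(cm, comb, cls, policy)
      expect_equal(got$n_evaluable, unname(want["n_evaluable"]))
      expect_equal(got$n_true_concordant, unname(want["n_true"]))
      expect_equal(got$n_false_concordant, unname(want["n_false"]))
      expect_equal(got$n_discordant, unname(want["n_discordant"]))
    }
  }
})

test_that("counts partition the evaluable set and rates follow", {
  set.seed(5)
  for (rep in 1:25) {
    cm <- random_call_matrix(30, 5)
    res <- combination_concordance(cm, colnames(cm$calls)[1:3], "all",
                                   sample(c("complete", "available"), 1))
    expect_equal(res$n_true_concordant + res$n_false_concordant +
                   res$n_discordant, res$n_evaluable)
    expect_lte(res$true_rate + res$false_rate, 1 + 1e-12)
  }
})

test_that("full concordance is non-increasing along nested combination chains", {
  set.seed(77)
  cm <- random_call_matrix(100, 6, miss = 0)
  algs <- colnames(cm$calls)
  prev_true <- prev_false <- Inf
  for (k in 1:6) {
    res <- combination_concordance(cm, algs[1:k], "all", "complete")
    expect_lte(res$true_rate, prev_true + 1e-12)
    expect_lte(res$false_rate, prev_false + 1e-12)
    prev_true <- res$true_rate; prev_false <- res$false_rate
  }
})

test_that("sweep produces one row per combination and class, deterministically", {
  set.seed(8)
  cm <- random_call_matrix(40, 5)
  tab <- sweep_combinations(cm, 3)
  expect_equal(nrow(tab), choose(5, 3) * 3L)
  expect_setequal(unique(tab$truth_class), c("benign", "pathogenic", "all"))
  # k = 1 gives one combination row per algorithm per class
  tab1 <- sweep_combinations(cm, 1)
  expect_equal(nrow(tab1), 5L * 3L)
  # identical rerun
  expect_identical(tab, sweep_combinations(cm, 3))
  # the 'all' row pools the class counts
  one <- tab[tab$combination == tab$combination[1], ]
  expect_equal(one$n_true_concordant[one$truth_class == "all"],
               sum(one$n_true_concordant[one$truth_class != "all"]))
  expect_equal(one$n_evaluable[one$truth_class == "all"],
               sum(one$n_evaluable[one$truth_class != "all"]))
})

test_that("results are invariant to variant reordering and algorithm relabeling", {
  set.seed(13)
  cm <- random_call_matrix(40, 4)
  res <- combination_concordance(cm, c("alg1", "alg3"), "all", "available")
  perm <- sample(40)
  cm2 <- call_matrix(cm$calls[perm, ], cm$truth[perm])
  res2 <- combination_concordance(cm2, c("alg1", "alg3"), "all", "available")
  expect_equal(res2[, -1], res[, -1], ignore_attr = TRUE)
  # relabel algorithms
  calls3 <- cm$calls; colnames(calls3) <- paste0("z", 1:4)
  cm3 <- call_matrix(calls3, cm$truth)
  res3 <- combination_concordance(cm3, c("z1", "z3"), "all", "available")
  expect_equal(res3[, -1], res[, -1], ignore_attr = TRUE)
})

test_that("majority opposition counts variants opposed by the call majority", {
  # 3 benign variants: opposed by 2/2, 1/2, 0/2 non-missing calls
  cm <- make_calls(c("D","D", "D","T", "T","T", "D","D"),
                   truth = c("benign", "benign", "benign", "pathogenic"),
                   n_alg = 2)
  mo <- majority_opposition(cm, "benign", 0.5)
  expect_equal(mo$count, 2L)       # >= 50% opposition: variants 1 and 2
  expect_equal(mo$denominator, 3L)
  expect_equal(mo$rate, 2 / 3)
  # all calls agree with truth -> zero
  agree <- make_calls(c("T","T", "D","D"),
                      truth = c("benign", "pathogenic"), n_alg = 2)
  expect_equal(majority_opposition(agree, "benign")$count, 0L)
  expect_equal(majority_opposition(agree, "benign")$rate, 0)
  # variants with zero non-missing calls leave the denominator
  cm2 <- make_calls(c(".",".", "D","D"), c("benign", "benign"), 2)
  expect_equal(majority_opposition(cm2, "benign")$denominator, 1L)
})

test_that("percentage formatting rounds half away from zero to one decimal", {
  expect_equal(format_pct(382 / 7346), "5.2")
  expect_equal(format_pct(2930 / 7473), "39.2")
  expect_equal(format_pct(0.0005), "0.1")   # half away from zero
  expect_equal(format_pct(0.10549), "10.5")
})
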