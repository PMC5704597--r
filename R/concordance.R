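#' Pairwise agreement between predictors
#'
#' For every unordered pair of algorithms, the fraction of variants (within
#' the requested truth class) on which both make a non-missing call and the
#' calls are equal. The denominator is the number of variants where both are
#' non-missing; pairs with an empty denominator get `NA` agreement and are
#' flagged in the `undefined` column.
#'
#' @param calls A [call_matrix()].
#' @param truth_class `"benign"`, `"pathogenic"` or `"all"`.
#' @return Data frame with columns `alg_a`, `alg_b`, `n_evaluable`,
#'   `agreement`, `undefined`.
#' @export
pairwise_agreement <- function(calls, truth_class = c("all", "benign", "pathogenic")) {
  stopifnot(inherits(calls, "call_matrix"))
  truth_class <- match.arg(truth_class)
  m <- calls$calls
  if (ncol(m) < 2L) stop("need at least 2 algorithms")
  if (truth_class != "all") m <- m[calls$truth == truth_class, , drop = FALSE]
  alg <- colnames(m)
  pairs <- utils::combn(alg, 2L)
  res <- apply(pairs, 2L, function(p) {
    a <- m[, p[1]]; b <- m[, p[2]]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    c(n = n, agree = if (n > 0) mean(a[ok] == b[ok]) else NA_real_)
  })
  data.frame(alg_a = pairs[1, ], alg_b = pairs[2, ],
             n_evaluable = as.integer(res["n", ]),
             agreement = res["agree", ],
             undefined = res["n", ] == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Welch test comparing benign vs pathogenic pairwise agreement
#'
#' Two-sided Welch (unequal variance) two-sample t-test on two sets of
#' pairwise agreement proportions, as used to ask whether predictors agree
#' less on benign than on pathogenic variants.
#'
#' @param benign_agreements,pathogenic_agreements Numeric vectors of
#'   agreement fractions (each of length >= 2 with nonzero variance).
#' @return List with `t`, `p`, `df`, `mean_benign`, `mean_pathogenic`.
#' @export
pairwise_difference_test <- function(benign_agreements, pathogenic_agreements) {
  b <- benign_agreements[!is.na(benign_agreements)]
  p <- pathogenic_agreements[!is.na(pathogenic_agreements)]
  if (length(b) < 2 || length(p) < 2)
    stop("need at least 2 agreement values per class")
  if (stats::var(b) == 0 && stats::var(p) == 0) {
    if (isTRUE(all.equal(mean(b), mean(p))))
      return(list(t = 0, p = 1, df = Inf,
                  mean_benign = mean(b), mean_pathogenic = mean(p)))
    stop("degenerate variance in both agreement sets")
  }
  tt <- stats::t.test(b, p, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_benign = mean(b), mean_pathogenic = mean(p))
}

#' Enumerate size-k algorithm combinations
#'
#' All size-`k` subsets in lexicographic order of the (sorted) algorithm
#' names, skipping subsets that contain both members of any exclusion pair
#' (used to drop combinations co-listing a metapredictor and its near-twin,
#' e.g. MetaSVM with MetaLR).
#'
#' @param algorithms Character vector of algorithm names.
#' @param k Combination size, `1 <= k <= length(algorithms)`.
#' @param exclusion_pairs List of length-2 character vectors.
#' @return Character matrix with `k` rows, one column per combination.
#' @export
enumerate_combinations <- function(algorithms, k, exclusion_pairs = list()) {
  algorithms <- sort(unique(as.character(algorithms)))
  if (k < 1 || k > length(algorithms))
    stop("k must be between 1 and ", length(algorithms))
  combos <- utils::combn(algorithms, k)
  if (length(exclusion_pairs)) {
    drop <- rep(FALSE, ncol(combos))
    for (pr in exclusion_pairs) {
      stopifnot(length(pr) == 2L)
      drop <- drop | (colSums(matrix(combos %in% pr, nrow = k)) == 2L)
    }
    combos <- combos[, !drop, drop = FALSE]
  }
  combos
}

# Shared counting kernel over a 0/1/NA integer call submatrix.
# complete policy: evaluable iff all members non-missing; available policy:
# evaluable iff >= 2 members non-missing, unanimity over the non-missing ones.
.concordance_counts <- function(sub, truth, missing_policy) {
  n_nonmiss <- rowSums(!is.na(sub))
  n_dam <- rowSums(sub == 1L, na.rm = TRUE)
  k <- ncol(sub)
  evaluable <- if (missing_policy == "complete") n_nonmiss == k else n_nonmiss >= 2L
  unan_dam <- evaluable & n_dam == n_nonmiss & n_nonmiss > 0L
  unan_tol <- evaluable & n_dam == 0L
  truth_dam <- truth == "pathogenic"
  true_conc <- (unan_dam & truth_dam) | (unan_tol & !truth_dam)
  false_conc <- (unan_dam & !truth_dam) | (unan_tol & truth_dam)
  c(n_evaluable = sum(evaluable),
    n_true = sum(true_conc),
    n_false = sum(false_conc),
    n_discordant = sum(evaluable) - sum(true_conc) - sum(false_conc))
}

#' Concordance of one algorithm combination with the truth labels
#'
#' A variant is *truly concordant* when every (counted) member makes the same
#' call and that call matches the ClinVar-style truth label
#' (damaging <-> pathogenic, tolerated <-> benign); *falsely concordant* when
#' the unanimous call opposes the truth; otherwise discordant. Under the
#' `"complete"` missing policy a variant is evaluable only if all members
#' have a call; under `"available"` it is evaluable if at least two members
#' have a call and unanimity is judged over the non-missing members.
#'
#' @param calls A [call_matrix()].
#' @param combination Character vector of member algorithm names.
#' @param truth_class `"benign"`, `"pathogenic"` or `"all"`.
#' @param missing_policy `"complete"` or `"available"`.
#' @return A one-row data frame of class `concordance_result`: `combination`,
#'   `truth_class`, `missing_policy`, `n_evaluable`, `n_true_concordant`,
#'   `n_false_concordant`, `n_discordant`, `true_rate`, `false_rate`.
#' @export
combination_concordance <- function(calls, combination,
                                    truth_class = c("all", "benign", "pathogenic"),
                                    missing_policy = c("complete", "available")) {
  stopifnot(inherits(calls, "call_matrix"))
  truth_class <- match.arg(truth_class)
  missing_policy <- match.arg(missing_policy)
  combination <- as.character(combination)
  if (!length(combination)) stop("empty combination")
  absent <- setdiff(combination, colnames(calls$calls))
  if (length(absent))
    stop("combination member(s) not in call matrix: ",
         paste(absent, collapse = ", "))
  m <- calls$calls
  tr <- calls$truth
  if (truth_class != "all") {
    keep <- tr == truth_class
    m <- m[keep, , drop = FALSE]
    tr <- tr[keep]
  }
  cnt <- .concordance_counts(m[, combination, drop = FALSE], tr, missing_policy)
  res <- data.frame(
    combination = paste(sort(combination), collapse = "+"),
    truth_class = truth_class,
    missing_policy = missing_policy,
    n_evaluable = unname(cnt["n_evaluable"]),
    n_true_concordant = unname(cnt["n_true"]),
    n_false_concordant = unname(cnt["n_false"]),
    n_discordant = unname(cnt["n_discordant"]),
    true_rate = if (cnt["n_evaluable"] > 0)
      unname(cnt["n_true"] / cnt["n_evaluable"]) else 0,
    false_rate = if (cnt["n_evaluable"] > 0)
      unname(cnt["n_false"] / cnt["n_evaluable"]) else 0,
    stringsAsFactors = FALSE
  )
  class(res) <- c("concordance_result", class(res))
  res
}

#' Sweep all size-k combinations
#'
#' Runs [combination_concordance()] for every size-`k` combination and each
#' truth class (benign, pathogenic, all), streaming over combinations so
#' memory stays proportional to the number of combinations. The `"all"` rows
#' pool both classes: (true concordant benign + pathogenic) /
#' (evaluable benign + pathogenic).
#'
#' @inheritParams combination_concordance
#' @param k Combination size.
#' @param exclusion_pairs Passed to [enumerate_combinations()].
#' @return Data frame with one row per combination x truth class, sorted by
#'   combination then class.
#' @export
sweep_combinations <- function(calls, k, missing_policy = c("complete", "available"),
                               exclusion_pairs = list()) {
  stopifnot(inherits(calls, "call_matrix"))
  missing_policy <- match.arg(missing_policy)
  combos <- enumerate_combinations(colnames(calls$calls), k, exclusion_pairs)
  classes <- c("benign", "pathogenic", "all")
  m <- calls$calls
  tr <- calls$truth
  split_idx <- list(benign = tr == "benign", pathogenic = tr == "pathogenic",
                    all = rep(TRUE, length(tr)))
  rows <- vector("list", ncol(combos) * length(classes))
  ri <- 0L
  for (ci in seq_len(ncol(combos))) {
    comb <- combos[, ci]
    sub <- m[, comb, drop = FALSE]
    for (cl in classes) {
      idx <- split_idx[[cl]]
      cnt <- .concordance_counts(sub[idx, , drop = FALSE], tr[idx],
                                 missing_policy)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        combination = paste(comb, collapse = "+"),
        truth_class = cl, missing_policy = missing_policy,
        n_evaluable = unname(cnt["n_evaluable"]),
        n_true_concordant = unname(cnt["n_true"]),
        n_false_concordant = unname(cnt["n_false"]),
        n_discordant = unname(cnt["n_discordant"]),
        true_rate = if (cnt["n_evaluable"] > 0)
          unname(cnt["n_true"] / cnt["n_evaluable"]) else 0,
        false_rate = if (cnt["n_evaluable"] > 0)
          unname(cnt["n_false"] / cnt["n_evaluable"]) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$combination, out$truth_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variants opposed by a majority of predictors
#'
#' Counts variants of the given truth class for which at least `fraction` of
#' the non-missing calls oppose the truth label (e.g. benign variants called
#' damaging by >= 50% of predictors). Variants with no non-missing call are
#' excluded from the denominator.
#'
#' @param calls A [call_matrix()].
#' @param truth_class `"benign"` or `"pathogenic"`.
#' @param fraction Opposition fraction threshold in (0, 1].
#' @return List with `count`, `denominator`, `rate`.
#' @export
majority_opposition <- function(calls, truth_class = c("benign", "pathogenic"),
                                fraction = 0.5) {
  stopifnot(inherits(calls, "call_matrix"), fraction > 0, fraction <= 1)
  truth_class <- match.arg(truth_class)
  m <- calls$calls[calls$truth == truth_class, , drop = FALSE]
  n_nonmiss <- rowSums(!is.na(m))
  opposing_call <- if (truth_class == "benign") 1L else 0L
  n_opp <- rowSums(m == opposing_call, na.rm = TRUE)
  denom_ok <- n_nonmiss > 0L
  hit <- denom_ok & (n_opp / pmax(n_nonmiss, 1L)) >= fraction
  list(count = sum(hit), denominator = sum(denom_ok),
       rate = if (sum(denom_ok) > 0) sum(hit) / sum(denom_ok) else 0)
}

#' Format a fraction as a percentage, half away from zero, one decimal
#'
#' Deterministic reporting helper: 0.0515 prints as "5.2". Raw fractions are
#' always retained in result tables; this only affects display.
#'
#' @param x Numeric fractions.
#' @param digits Decimal places (default 1).
#' @return Character vector of percentages without the \% sign.
#' @export
format_pct <- function(x, digits = 1L) {
  p <- x * 100
  f <- 10^digits
  sprintf(paste0("%.", digits, "f"), sign(p) * floor(abs(p) * f + 0.5) / f)
}
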