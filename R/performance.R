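#' Mann-Whitney AUC of a direction-aligned score
#'
#' The empirical AUC: the mean over all (pathogenic, benign) pairs of
#' \[score_pos > score_neg\] + 1/2 \[score_pos = score_neg\], computed via
#' midranks in O(n log n). Rows with a missing score are dropped. Scores are
#' assumed direction-aligned (higher = more damaging); an AUC below 0.5 is
#' reported as-is so a mis-specified direction stays visible.
#'
#' @param scores Numeric vector (`NA` allowed).
#' @param truth Character vector of `"benign"`/`"pathogenic"` (or a logical
#'   vector, `TRUE` = positive).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth)
    stopifnot(all(truth %in% c("benign", "pathogenic")))
    truth <- truth == "pathogenic"
  }
  ok <- !is.na(scores) & !is.na(truth)
  x <- scores[ok]; y <- truth[ok]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative with non-missing scores")
  r <- rank(x, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement values: V10 per positive, V01 per negative.
.delong_placements <- function(x, y) {
  n_pos <- sum(y); n_neg <- sum(!y)
  r_all <- rank(x, ties.method = "average")
  r_pos <- rank(x[y], ties.method = "average")
  r_neg <- rank(x[!y], ties.method = "average")
  v10 <- (r_all[y] - r_pos) / n_neg
  v01 <- 1 - (r_all[!y] - r_neg) / n_pos
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUC with a confidence interval
#'
#' `method = "delong"` gives an asymptotic normal interval built from the
#' DeLong variance of the placement values, computed on the logit scale
#' (delta method) and back-transformed — the variance-stabilized form keeps
#' the interval inside (0, 1) and is better calibrated in moderate samples
#' than the untransformed interval, which it falls back to when the AUC or
#' its variance is degenerate. `method = "bootstrap"` gives the percentile
#' interval from stratified (within-class) resampling. Both ends are clipped
#' to \[0, 1\].
#'
#' @inheritParams auc
#' @param level Confidence level (default 0.99).
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (bootstrap method only).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `auc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `ci_level`, `n_pos`, `n_neg`, `method`.
#' @export
auc_ci <- function(scores, truth, level = 0.99,
                   method = c("delong", "bootstrap"),
                   n_boot = 2000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(level > 0, level < 1)
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth) == "pathogenic"
  }
  ok <- !is.na(scores) & !is.na(truth)
  x <- scores[ok]; y <- truth[ok]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative with non-missing scores")

  if (method == "delong") {
    pl <- .delong_placements(x, y)
    v <- stats::var(pl$v10) / n_pos + stats::var(pl$v01) / n_neg
    z <- stats::qnorm(1 - (1 - level) / 2)
    a <- pl$auc
    if (v > 0 && a > 0 && a < 1) {
      lg <- stats::qlogis(a)
      se_lg <- sqrt(v) / (a * (1 - a))
      ci <- stats::plogis(c(lg - z * se_lg, lg + z * se_lg))
    } else {
      half <- z * sqrt(v)
      ci <- c(a - half, a + half)
    }
  } else {
    if (n_boot < 100) warning("n_boot < 100 gives unstable percentile intervals")
    if (!is.null(seed)) set.seed(seed)
    pos <- x[y]; neg <- x[!y]
    boots <- vapply(seq_len(n_boot), function(i) {
      auc(c(sample(pos, n_pos, replace = TRUE),
            sample(neg, n_neg, replace = TRUE)),
          c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
    }, numeric(1))
    a <- auc(x, y)
    ci <- unname(stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  structure(list(auc = a, ci_low = max(0, min(ci)), ci_high = min(1, max(ci)),
                 ci_level = level, n_pos = n_pos, n_neg = n_neg,
                 method = method),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (%d%% CI %.4f-%.4f, %s; %d pathogenic / %d benign)\n",
              x$auc, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$method, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired stratified-bootstrap comparison of two AUCs
#'
#' Tests the difference between the AUCs of two predictors scored on the
#' same variants. Only rows where both scores and the truth are non-missing
#' enter. Each bootstrap replicate resamples variants within each truth
#' class (so every replicate keeps the original class sizes), recomputes
#' both AUCs, and the two-sided p-value comes from the normal approximation
#' z = observed delta / sd(bootstrap deltas), as in the standard bootstrap
#' ROC comparison.
#'
#' @param scores_a,scores_b Numeric vectors on the same variants,
#'   direction-aligned.
#' @inheritParams auc
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return List with `delta_auc` (a minus b), `auc_a`, `auc_b`, `p`,
#'   `n_boot`, `n_pos`, `n_neg`.
#' @export
compare_auc <- function(scores_a, scores_b, truth, n_boot = 10000L, seed = NULL) {
  if (is.character(truth) || is.factor(truth))
    truth <- as.character(truth) == "pathogenic"
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(truth)
  a <- scores_a[ok]; b <- scores_b[ok]; y <- truth[ok]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative with pairwise-complete scores")
  auc_a <- auc(a, y); auc_b <- auc(b, y)
  delta <- auc_a - auc_b
  if (!is.null(seed)) set.seed(seed)
  ipos <- which(y); ineg <- which(!y)
  deltas <- vapply(seq_len(n_boot), function(i) {
    idx <- c(sample(ipos, n_pos, replace = TRUE),
             sample(ineg, n_neg, replace = TRUE))
    auc(a[idx], y[idx]) - auc(b[idx], y[idx])
  }, numeric(1))
  s <- stats::sd(deltas)
  p <- if (s == 0) {
    if (delta == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta / s))
  }
  list(delta_auc = delta, auc_a = auc_a, auc_b = auc_b, p = p,
       n_boot = n_boot, n_pos = n_pos, n_neg = n_neg)
}

#' ROC-optimal cutpoint and operating characteristics
#'
#' Scans every unique observed score as a candidate damaging-inclusive
#' cutoff (call damaging when score >= cutoff, scores direction-aligned)
#' and returns the one maximizing the Youden index
#' (sensitivity + specificity - 1). Ties are broken toward higher
#' specificity, then toward the higher cutoff. PPV and NPV are computed at
#' the sample prevalence.
#'
#' @inheritParams auc
#' @param criterion Only `"youden"` is implemented.
#' @return Object of class `cutpoint_result`: list with `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden`, `criterion`.
#' @export
optimal_cutpoint <- function(scores, truth, criterion = "youden") {
  criterion <- match.arg(criterion, "youden")
  if (is.character(truth) || is.factor(truth))
    truth <- as.character(truth) == "pathogenic"
  ok <- !is.na(scores) & !is.na(truth)
  x <- scores[ok]; y <- truth[ok]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative with non-missing scores")
  cands <- sort(unique(x), decreasing = TRUE)
  best <- NULL
  for (cut in cands) {
    called <- x >= cut
    sens <- sum(called & y) / n_pos
    spec <- sum(!called & !y) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && spec > best$specificity + 1e-12)) {
      tp <- sum(called & y); fp <- sum(called & !y)
      tn <- sum(!called & !y); fn <- sum(!called & y)
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                   youden = j, criterion = criterion)
    }
  }
  structure(best, class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("cutoff %.4g (youden): sens %.3f spec %.3f ppv %.3f npv %.3f\n",
              x$cutoff, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Per-algorithm AUC table for a prediction matrix
#'
#' Complete-case within each algorithm (its missing rows are dropped for its
#' own AUC, matching per-algorithm variable n).
#'
#' @param matrix A [prediction_matrix()], direction-aligned (e.g. from
#'   [rank_normalize()]).
#' @inheritParams auc_ci
#' @return Data frame with one row per algorithm: `algorithm`, `auc`,
#'   `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
auc_table <- function(matrix, level = 0.99, method = "delong") {
  stopifnot(inherits(matrix, "prediction_matrix"))
  rows <- lapply(colnames(matrix$scores), function(a) {
    r <- auc_ci(matrix$scores[, a], matrix$truth, level = level,
                method = method)
    data.frame(algorithm = a, auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high, n_pos = r$n_pos, n_neg = r$n_neg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc), , drop = FALSE]
}
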