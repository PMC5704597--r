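#' Map a categorical predictor label to a binary call
#'
#' Looks the label up in the spec's `categorical_map`; labels mapped to `NA`
#' (e.g. LRT's "Unknown") and labels absent from the map are treated as no
#' data (the latter with a warning, since dbNSFP label sets drift across
#' versions).
#'
#' @param label Character vector of raw labels (`NA` allowed).
#' @param spec An [algorithm_spec()] of categorical kind.
#' @return Character vector of `"damaging"`, `"tolerated"` or `NA`.
#' @export
map_categorical <- function(label, spec) {
  stopifnot(inherits(spec, "algorithm_spec"), spec$kind == "categorical")
  label <- as.character(label)
  out <- unname(spec$categorical_map[label])
  unknown <- !is.na(label) & !(label %in% names(spec$categorical_map))
  if (any(unknown))
    warning(sum(unknown), " unknown label(s) for ", spec$name,
            " treated as missing: ",
            paste(utils::head(unique(label[unknown]), 3), collapse = ", "))
  out
}

#' Binarize a numeric score against a predictor's threshold
#'
#' For `higher_damaging` predictors a score at or above the threshold is
#' damaging; for `lower_damaging`, at or below. The boundary is
#' damaging-inclusive. Missing or non-finite scores give `NA` (non-finite
#' with a warning).
#'
#' @param score Numeric vector (`NA` allowed).
#' @param spec An [algorithm_spec()] of numeric kind with a finite threshold.
#' @return Character vector of `"damaging"`, `"tolerated"` or `NA`.
#' @export
binarize_score <- function(score, spec) {
  stopifnot(inherits(spec, "algorithm_spec"), spec$kind == "numeric")
  if (!is.finite(spec$threshold))
    stop("algorithm '", spec$name, "' has no finite threshold")
  score <- as.numeric(score)
  bad <- !is.na(score) & !is.finite(score)
  if (any(bad)) {
    warning(sum(bad), " non-finite score(s) for ", spec$name,
            " treated as missing")
    score[bad] <- NA_real_
  }
  damaging <- if (spec$direction == "higher_damaging")
    score >= spec$threshold else score <= spec$threshold
  ifelse(is.na(score), NA_character_,
         ifelse(damaging, "damaging", "tolerated"))
}

#' Most damaging value among per-transcript scores
#'
#' Reduces a multi-transcript cell to a single score: the minimum of the
#' non-missing values for `lower_damaging` predictors, the maximum for
#' `higher_damaging`. All-missing input gives `NA`.
#'
#' @param values Numeric vector (one `;`-separated cell, `NA` allowed).
#' @param spec An [algorithm_spec()].
#' @return A single numeric value or `NA`.
#' @export
most_damaging <- function(values, spec) {
  stopifnot(inherits(spec, "algorithm_spec"))
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  if (spec$direction == "lower_damaging") min(values) else max(values)
}

#' Binarize a prediction matrix into a call matrix
#'
#' Applies [binarize_score()] to numeric columns and [map_categorical()] to
#' label columns, element-wise. Algorithms without a publicly available
#' threshold (`has_public_threshold = FALSE`) are excluded; their names are
#' recorded in `attr(, "excluded")` and messaged.
#'
#' @param matrix A [prediction_matrix()].
#' @param specs Named list of [algorithm_spec()]s covering the matrix's
#'   algorithms.
#' @return A [call_matrix()].
#' @export
build_call_matrix <- function(matrix, specs) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  alg <- c(colnames(matrix$scores),
           if (!is.null(matrix$labels)) colnames(matrix$labels))
  missing_spec <- setdiff(alg, names(specs))
  if (length(missing_spec))
    stop("no spec for algorithm(s): ", paste(missing_spec, collapse = ", "))
  usable <- alg[vapply(specs[alg], function(s)
    s$has_public_threshold || s$kind == "categorical", logical(1))]
  excluded <- setdiff(alg, usable)
  if (length(excluded))
    message("excluded (no public threshold): ", paste(excluded, collapse = ", "))
  if (!length(usable)) stop("no algorithms with a usable threshold remain")

  calls <- matrix(NA_integer_, nrow(matrix$scores), length(usable),
                  dimnames = list(rownames(matrix$scores), usable))
  for (a in usable) {
    spec <- specs[[a]]
    cl <- if (spec$kind == "numeric") {
      binarize_score(matrix$scores[, a], spec)
    } else {
      map_categorical(matrix$labels[, a], spec)
    }
    if (all(is.na(cl)))
      warning("algorithm ", a, " produced no calls (all missing)")
    calls[, a] <- ifelse(is.na(cl), NA_integer_, as.integer(cl == "damaging"))
  }
  out <- call_matrix(calls, matrix$truth, gene = matrix$gene)
  attr(out, "excluded") <- excluded
  out
}

#' Direction-aligned fractional rank normalization
#'
#' Per algorithm, scores of `lower_damaging` predictors are negated, then all
#' non-missing values are converted to fractional ranks in (0, 1] (average
#' ranks on ties, divided by the number of non-missing values). Afterwards a
#' higher value always means a more damaging prediction, and any strictly
#' increasing transform of a column leaves the result unchanged. A constant
#' column becomes 0.5 everywhere with a warning.
#'
#' @param matrix A [prediction_matrix()].
#' @param specs Named list of [algorithm_spec()]s (for direction); columns
#'   without a spec are assumed `higher_damaging`.
#' @return A [prediction_matrix()] of rank-normalized scores (labels, if any,
#'   are dropped), with attribute `rank_normalized = TRUE`.
#' @export
rank_normalize <- function(matrix, specs = NULL) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  sc <- matrix$scores
  for (a in colnames(sc)) {
    x <- sc[, a]
    ok <- !is.na(x)
    if (!any(ok)) next
    dir <- if (!is.null(specs) && a %in% names(specs))
      specs[[a]]$direction else "higher_damaging"
    v <- if (dir == "lower_damaging") -x[ok] else x[ok]
    if (length(unique(v)) == 1L)
      warning("constant score column '", a,
              "' carries no ranking information")
    sc[ok, a] <- rank(v, ties.method = "average") / sum(ok)
  }
  out <- prediction_matrix(sc, matrix$truth, gene = matrix$gene)
  attr(out, "rank_normalized") <- TRUE
  out
}
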