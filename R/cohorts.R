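#' Evaluation cohort
#'
#' A named set of variant keys plus a human-readable construction recipe
#' (provenance). Cohorts are always subsets of the ingested variants.
#'
#' @param name Cohort name.
#' @param keys Character vector of variant keys.
#' @param provenance Non-empty recipe text.
#' @return Object of class `cohort`.
#' @export
cohort <- function(name, keys, provenance) {
  stopifnot(is.character(name), nzchar(name),
            is.character(provenance), nzchar(provenance))
  structure(list(name = name, keys = unique(as.character(keys)),
                 provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d variants\n  %s\n", x$name, length(x$keys),
              x$provenance))
  invisible(x)
}

#' Variants new to a snapshot
#'
#' Variants of the newer release whose key is absent from the older release
#' (key match only; classification changes do not resurrect a key). Class
#' labels come from the newer snapshot. Used to build
#' circularity-controlled cohorts of variants deposited after a predictor's
#' training-data cutoff.
#'
#' @param newer,older Variant-record data frames (see
#'   [read_clinvar_summary()]) with a `key` column.
#' @param name Cohort name.
#' @return A [cohort()].
#' @export
snapshot_diff <- function(newer, older, name = "snapshot_diff") {
  keys <- setdiff(newer$key, older$key)
  cohort(name, keys,
         sprintf("variants present in newer snapshot (n=%d) and absent from older (n=%d)",
                 nrow(newer), nrow(older)))
}

#' Remove training-set variants from a cohort
#'
#' Set difference against a predictor's training-set keys (type 1
#' circularity control).
#'
#' @param x A [cohort()].
#' @param training_keys Character vector of variant keys to remove.
#' @param label Text appended to the provenance.
#' @return A [cohort()].
#' @export
exclude_training <- function(x, training_keys, label = "training set") {
  stopifnot(inherits(x, "cohort"))
  keys <- setdiff(x$keys, training_keys)
  cohort(x$name, keys,
         paste0(x$provenance, "; minus ", label, " (", length(x$keys) - length(keys),
                " removed)"))
}

#' Stratify variants by gene-level annotation
#'
#' Splits variants into cohorts by a gene attribute:
#' \describe{
#'   \item{constraint}{ExAC missense Z bins: high `[2.5, Inf)`,
#'     intermediate `[0, 2.5)`, low `(-Inf, 0)`.}
#'   \item{inheritance}{dominant-only and recessive-only gene cohorts.}
#'   \item{cancer}{oncogene and tumor-suppressor cohorts (GOF vs LOF
#'     proxies).}
#' }
#' Variants in genes absent from the annotation (or with a missing
#' attribute) land in no cohort; their count is recorded in
#' `attr(, "n_unannotated")`.
#'
#' @param variants Variant-record data frame with `key` and `gene_symbol`.
#' @param annotations Data frame with one row per `gene_symbol` and columns
#'   `missense_z` (numeric), `inheritance`
#'   (`dominant`/`recessive`/`both`/`unknown`), `cancer_class`
#'   (`oncogene`/`tsg`/`neither`/`unknown`) as required by the scheme.
#' @param scheme `"constraint"`, `"inheritance"` or `"cancer"`.
#' @return Named list of [cohort()]s with attribute `n_unannotated`.
#' @export
stratify_genes <- function(variants, annotations,
                           scheme = c("constraint", "inheritance", "cancer")) {
  scheme <- match.arg(scheme)
  if (anyDuplicated(annotations$gene_symbol))
    stop("annotations must have one row per gene_symbol")
  idx <- match(variants$gene_symbol, annotations$gene_symbol)

  out <- switch(scheme,
    constraint = {
      z <- annotations$missense_z[idx]
      list(
        high_constraint = cohort("high_constraint",
          variants$key[!is.na(z) & z >= 2.5],
          "genes with missense Z >= 2.5"),
        intermediate_constraint = cohort("intermediate_constraint",
          variants$key[!is.na(z) & z >= 0 & z < 2.5],
          "genes with missense Z in [0, 2.5)"),
        low_constraint = cohort("low_constraint",
          variants$key[!is.na(z) & z < 0],
          "genes with missense Z < 0")
      )
    },
    inheritance = {
      mode <- annotations$inheritance[idx]
      list(
        dominant = cohort("dominant", variants$key[!is.na(mode) & mode == "dominant"],
                          "genes with dominant inheritance (per both sources)"),
        recessive = cohort("recessive", variants$key[!is.na(mode) & mode == "recessive"],
                           "genes with recessive inheritance (per both sources)")
      )
    },
    cancer = {
      cls <- annotations$cancer_class[idx]
      list(
        oncogene = cohort("oncogene", variants$key[!is.na(cls) & cls == "oncogene"],
                          "oncogenes (GOF proxy)"),
        tsg = cohort("tsg", variants$key[!is.na(cls) & cls == "tsg"],
                     "tumor suppressor genes (LOF proxy)")
      )
    })
  annotated_attr <- switch(scheme, constraint = "missense_z",
                           inheritance = "inheritance", cancer = "cancer_class")
  n_unann <- sum(is.na(idx) | is.na(annotations[[annotated_attr]][idx]))
  attr(out, "n_unannotated") <- n_unann
  out
}

#' Per-gene class-balanced subset
#'
#' For every gene let m = min(benign count, pathogenic count); genes with
#' m = 0 are dropped, otherwise m benign and m pathogenic variants are kept,
#' chosen uniformly at random with the seeded RNG. The result controls
#' type 2 circularity: no gene contributes an unbalanced class composition.
#'
#' @param variants Data frame with `key`, `gene_symbol`, `clin_class`
#'   (benign/pathogenic).
#' @param seed Required RNG seed.
#' @return A [cohort()].
#' @export
balanced_subset <- function(variants, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  keys <- character(0)
  for (g in sort(unique(variants$gene_symbol))) {
    vg <- variants[variants$gene_symbol == g, , drop = FALSE]
    b <- vg$key[vg$clin_class == "benign"]
    p <- vg$key[vg$clin_class == "pathogenic"]
    m <- min(length(b), length(p))
    if (m == 0) next
    keys <- c(keys,
              if (length(b) == m) b else sample(b, m),
              if (length(p) == m) p else sample(p, m))
  }
  cohort("balanced", keys,
         sprintf("per-gene class-balanced subset (seed %s)", seed))
}

#' Complete-case restriction of a matrix
#'
#' Removes variants with any missing value among the chosen algorithms.
#'
#' @param matrix A [prediction_matrix()] or [call_matrix()].
#' @param algorithms Algorithm subset (default: all).
#' @return Same type as `matrix`.
#' @export
complete_case <- function(matrix, algorithms = NULL) {
  if (inherits(matrix, "prediction_matrix")) {
    m <- matrix$scores
  } else if (inherits(matrix, "call_matrix")) {
    m <- matrix$calls
  } else stop("matrix must be a prediction_matrix or call_matrix")
  if (is.null(algorithms)) algorithms <- colnames(m)
  stopifnot(all(algorithms %in% colnames(m)))
  keep <- stats::complete.cases(m[, algorithms, drop = FALSE])
  if (!any(keep)) warning("no complete-case variants remain")
  subset_variants(matrix, rownames(m)[keep])
}

#' Subset a matrix to a set of variant keys (e.g. a cohort)
#'
#' @param matrix A [prediction_matrix()] or [call_matrix()].
#' @param keys Character vector of variant keys, or a [cohort()].
#' @return Same type as `matrix`, restricted (row order preserved).
#' @export
subset_variants <- function(matrix, keys) {
  if (inherits(keys, "cohort")) keys <- keys$keys
  if (inherits(matrix, "prediction_matrix")) {
    keep <- rownames(matrix$scores) %in% keys
    prediction_matrix(matrix$scores[keep, , drop = FALSE],
                      matrix$truth[keep],
                      gene = if (!is.null(matrix$gene)) matrix$gene[keep],
                      labels = if (!is.null(matrix$labels))
                        matrix$labels[keep, , drop = FALSE])
  } else if (inherits(matrix, "call_matrix")) {
    keep <- rownames(matrix$calls) %in% keys
    call_matrix(matrix$calls[keep, , drop = FALSE], matrix$truth[keep],
                gene = if (!is.null(matrix$gene)) matrix$gene[keep])
  } else stop("matrix must be a prediction_matrix or call_matrix")
}
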