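#' Prediction and call matrices
#'
#' A `prediction_matrix` holds continuous predictor scores for a set of
#' variants: a numeric matrix (variants in rows, algorithms in columns) with
#' `NA` as the explicit missing state, a per-variant truth label
#' (`"benign"`/`"pathogenic"`), and optionally a per-variant gene symbol.
#' A `call_matrix` is its binarized counterpart with `"damaging"`/
#' `"tolerated"`/`NA` calls, derived deterministically by
#' [build_call_matrix()].
#'
#' @param scores Numeric matrix with unique rownames (variant keys) and
#'   colnames (algorithm names); `NA` encodes missing.
#' @param truth Character/factor vector of `"benign"`/`"pathogenic"`, one per
#'   row of `scores`.
#' @param gene Optional character vector of gene symbols, one per variant.
#' @param labels Optional character matrix of raw categorical labels (same
#'   rows as `scores`; columns are the categorical algorithms). Used by
#'   [build_call_matrix()] for label-valued predictors.
#' @return An object of class `prediction_matrix`.
#' @export
prediction_matrix <- function(scores, truth, gene = NULL, labels = NULL) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores must carry variant rownames and algorithm colnames")
  if (anyDuplicated(rownames(scores)))
    stop("variant keys must be unique")
  truth <- as.character(truth)
  if (length(truth) != nrow(scores))
    stop("truth must have one label per variant")
  if (!all(truth %in% c("benign", "pathogenic")))
    stop("truth labels must be 'benign' or 'pathogenic'")
  if (!is.null(gene)) {
    gene <- as.character(gene)
    stopifnot(length(gene) == nrow(scores))
    names(gene) <- rownames(scores)
  }
  if (!is.null(labels)) {
    stopifnot(is.matrix(labels), is.character(labels),
              nrow(labels) == nrow(scores), !is.null(colnames(labels)))
    rownames(labels) <- rownames(scores)
  }
  names(truth) <- rownames(scores)
  structure(list(scores = scores, truth = truth, gene = gene, labels = labels),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("<prediction_matrix> %d variants x %d algorithms\n",
              nrow(x$scores), ncol(x$scores)))
  tb <- table(x$truth)
  cat(sprintf("  truth: %s benign, %s pathogenic; %.1f%% cells missing\n",
              tb[["benign"]] %||% 0, tb[["pathogenic"]] %||% 0,
              100 * mean(is.na(x$scores))))
  invisible(x)
}

#' @export
dim.prediction_matrix <- function(x) dim(x$scores)

#' Construct a call matrix directly
#'
#' Mostly used by [build_call_matrix()] and by tests; `calls` uses integer
#' coding internally (1 = damaging, 0 = tolerated, `NA` = missing).
#'
#' @param calls Character (`"damaging"`/`"tolerated"`/`NA`) or 0/1 integer
#'   matrix with variant rownames and algorithm colnames.
#' @inheritParams prediction_matrix
#' @return An object of class `call_matrix`.
#' @export
call_matrix <- function(calls, truth, gene = NULL) {
  if (is.character(calls)) {
    m <- matrix(NA_integer_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
    m[calls == "damaging"] <- 1L
    m[calls == "tolerated"] <- 0L
    bad <- !is.na(calls) & !(calls %in% c("damaging", "tolerated"))
    if (any(bad)) stop("calls must be 'damaging', 'tolerated' or NA")
    calls <- m
  }
  stopifnot(is.matrix(calls))
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L) | is.na(calls)))
    stop("integer calls must be 0, 1 or NA")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must carry variant rownames and algorithm colnames")
  truth <- as.character(truth)
  stopifnot(length(truth) == nrow(calls),
            all(truth %in% c("benign", "pathogenic")))
  names(truth) <- rownames(calls)
  if (!is.null(gene)) {
    gene <- as.character(gene)
    stopifnot(length(gene) == nrow(calls))
    names(gene) <- rownames(calls)
  }
  structure(list(calls = calls, truth = truth, gene = gene),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("<call_matrix> %d variants x %d algorithms\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  damaging calls: %.1f%%; missing: %.1f%%\n",
              100 * mean(x$calls == 1L, na.rm = TRUE),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.call_matrix <- function(x) dim(x$calls)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / read a prediction matrix (TSV + JSON sidecar)
#'
#' The TSV holds one row per variant: `variant`, `truth`, optional `gene`,
#' then one column per algorithm with `.` for missing. The JSON sidecar
#' records provenance (algorithm order, truth counts). The round trip is
#' bit-exact: scores are written with full precision.
#'
#' @param x A `prediction_matrix`.
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_prediction_matrix <- function(x, path) {
  stopifnot(inherits(x, "prediction_matrix"))
  sc <- x$scores
  chr <- matrix(vapply(sc, function(v) {
    if (is.na(v)) "." else sprintf("%.17g", v)
  }, character(1)), nrow(sc), ncol(sc), dimnames = dimnames(sc))
  df <- data.frame(variant = rownames(sc), truth = unname(x$truth),
                   stringsAsFactors = FALSE)
  if (!is.null(x$gene)) df$gene <- unname(x$gene)
  df <- cbind(df, as.data.frame(chr, stringsAsFactors = FALSE))
  if (!is.null(x$labels)) {
    lab <- x$labels
    lab[is.na(lab)] <- "."
    df <- cbind(df, as.data.frame(lab, stringsAsFactors = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    algorithms = colnames(sc),
    label_algorithms = if (!is.null(x$labels)) colnames(x$labels),
    n_variants = nrow(sc),
    truth_counts = as.list(table(x$truth)),
    has_gene = !is.null(x$gene)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_prediction_matrix
#' @export
read_prediction_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "")
  meta_cols <- intersect(c("variant", "truth", "gene"), names(df))
  lab_cols <- character(0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    lab_cols <- intersect(as.character(meta$label_algorithms %||% character(0)),
                          names(df))
  }
  alg_cols <- setdiff(names(df), c(meta_cols, lab_cols))
  sc <- matrix(NA_real_, nrow(df), length(alg_cols),
               dimnames = list(df$variant, alg_cols))
  for (a in alg_cols) {
    v <- df[[a]]
    keep <- !(v == "." | v == "")
    sc[keep, a] <- as.numeric(v[keep])
  }
  labels <- NULL
  if (length(lab_cols)) {
    labels <- as.matrix(df[lab_cols])
    labels[labels == "."] <- NA_character_
    rownames(labels) <- df$variant
  }
  prediction_matrix(sc, df$truth, gene = if ("gene" %in% names(df)) df$gene,
                    labels = labels)
}
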