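#' Algorithm specification
#'
#' An `algorithm_spec` describes how one predictor's raw output maps to a
#' direction-aligned score and a binary damaging/tolerated call. Numeric
#' predictors carry a decision threshold and a direction (whether higher or
#' lower scores are more damaging); categorical predictors carry a label map
#' collapsing their output classes to `"damaging"`, `"tolerated"` or `NA`
#' (no data).
#'
#' @param name Algorithm name (must be unique within a registry).
#' @param kind `"numeric"` or `"categorical"`.
#' @param direction `"higher_damaging"` or `"lower_damaging"`. Required for
#'   numeric predictors; for categorical predictors it only matters if a
#'   numeric companion score is rank-normalized.
#' @param threshold Finite decision threshold (numeric kind only). The
#'   boundary is damaging-inclusive: a score exactly at the threshold is
#'   called damaging.
#' @param categorical_map Named character vector mapping raw labels to
#'   `"damaging"`, `"tolerated"` or `NA_character_` (categorical kind only).
#' @param family One of `"conservation"`, `"function"`, `"metapredictor"`.
#' @param has_public_threshold Logical; predictors without a publicly
#'   recommended threshold are excluded from binary-call matrices but still
#'   participate in score-based (ROC, clustering) analyses.
#'
#' @return An object of class `algorithm_spec`.
#' @export
algorithm_spec <- function(name, kind = c("numeric", "categorical"),
                           direction = c("higher_damaging", "lower_damaging"),
                           threshold = NA_real_, categorical_map = NULL,
                           family = c("function", "conservation", "metapredictor"),
                           has_public_threshold = TRUE) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "numeric") {
    if (has_public_threshold && !is.finite(threshold))
      stop("numeric algorithm '", name, "' with a public threshold needs a finite threshold")
  } else {
    if (is.null(categorical_map) || is.null(names(categorical_map)))
      stop("categorical algorithm '", name, "' needs a named categorical_map")
    bad <- !(categorical_map %in% c("damaging", "tolerated") | is.na(categorical_map))
    if (any(bad))
      stop("categorical_map values must be 'damaging', 'tolerated' or NA; offending: ",
           paste(unique(categorical_map[bad]), collapse = ", "))
  }
  structure(
    list(name = name, kind = kind, direction = direction,
         threshold = as.numeric(threshold),
         categorical_map = categorical_map, family = family,
         has_public_threshold = isTRUE(has_public_threshold)),
    class = "algorithm_spec"
  )
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf("<algorithm_spec> %s [%s, %s]\n", x$name, x$kind, x$family))
  if (x$kind == "numeric") {
    cat(sprintf("  direction: %s  threshold: %s  public threshold: %s\n",
                x$direction, format(x$threshold), x$has_public_threshold))
  } else {
    cat("  labels: ",
        paste(sprintf("%s->%s", names(x$categorical_map),
                      ifelse(is.na(x$categorical_map), "NA", x$categorical_map)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read an algorithm registry from YAML
#'
#' The registry is a YAML list of entries with fields `name`, `kind`,
#' `direction`, `threshold`, `labels` (a map label -> damaging/tolerated/NA),
#' `family` and `has_public_threshold`. Every field is overridable by editing
#' the file; the thresholds in force are logged into analysis outputs.
#'
#' @param path Path to a YAML registry; defaults to the registry shipped with
#'   the package.
#' @return A named list of [algorithm_spec()] objects.
#' @export
read_algorithm_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "algorithms.yaml", package = "concordkit",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(e) {
    cmap <- NULL
    if (!is.null(e$labels)) {
      cmap <- vapply(e$labels, function(v) {
        if (is.null(v) || identical(v, "NA")) NA_character_ else as.character(v)
      }, character(1))
    }
    algorithm_spec(
      name = e$name,
      kind = if (!is.null(e$kind)) e$kind else "numeric",
      direction = if (!is.null(e$direction)) e$direction else "higher_damaging",
      threshold = if (!is.null(e$threshold)) as.numeric(e$threshold) else NA_real_,
      categorical_map = cmap,
      family = if (!is.null(e$family)) e$family else "function",
      has_public_threshold = if (!is.null(e$has_public_threshold))
        isTRUE(e$has_public_threshold) else TRUE
    )
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs)))
    stop("duplicate algorithm names in registry: ",
         paste(unique(names(specs)[duplicated(names(specs))]), collapse = ", "))
  specs
}

#' The default 25-algorithm registry
#'
#' Convenience wrapper around [read_algorithm_registry()] for the registry
#' shipped with the package: 18 predictors with publicly recommended
#' thresholds (so they can be binarized) and 7 conservation/functional-genomics
#' scores without one (score-only analyses).
#'
#' @return A named list of [algorithm_spec()] objects.
#' @export
default_algorithm_registry <- function() read_algorithm_registry()
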