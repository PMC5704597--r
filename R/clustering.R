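#' Clustering configuration
#'
#' Settings for the bootstrap-supported hierarchical clustering of
#' predictors: Euclidean distance between algorithm columns, Ward.D2
#' agglomeration, and a multiscale bootstrap over resample sizes
#' `ceiling(r * n_variants)` for scale factors `r`.
#'
#' @param scales Positive scale factors; must include 1 (default
#'   `seq(0.5, 1.4, by = 0.1)`).
#' @param n_boot_per_scale Bootstrap replicates per scale (the headline
#'   replicate total is `length(scales) * n_boot_per_scale`; the default
#'   5000 x 10 scales = 50,000).
#' @param au_threshold AU support required to call a cluster stable
#'   (default 0.99).
#' @param seed RNG seed for the bootstrap.
#' @return List of class `cluster_config`.
#' @export
cluster_config <- function(scales = seq(0.5, 1.4, by = 0.1),
                           n_boot_per_scale = 5000L,
                           au_threshold = 0.99, seed = 1L) {
  stopifnot(all(scales > 0), n_boot_per_scale >= 1,
            au_threshold > 0, au_threshold <= 1)
  if (!any(abs(scales - 1) < 1e-9))
    stop("scales must include r = 1")
  structure(list(distance = "euclidean", linkage = "ward_d2",
                 scales = scales,
                 n_boot_per_scale = as.integer(n_boot_per_scale),
                 au_threshold = au_threshold, seed = seed),
            class = "cluster_config")
}

# hclust on algorithm columns; complete-case variants only.
.cluster_once <- function(sc) {
  d <- stats::dist(t(sc), method = "euclidean")
  stats::hclust(d, method = "ward.D2")
}

# Member sets of every internal node of an hclust tree, as sorted
# label-index strings (canonical clade ids).
.clade_ids <- function(hc) {
  n <- length(hc$labels %||% hc$order)
  sets <- vector("list", nrow(hc$merge))
  ids <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    mem <- unlist(lapply(hc$merge[i, ], function(j) {
      if (j < 0) -j else sets[[j]]
    }))
    sets[[i]] <- mem
    ids[i] <- paste(sort(mem), collapse = ",")
  }
  list(sets = sets, ids = ids)
}

#' Ward.D2 dendrogram of predictors
#'
#' Clusters the algorithms (columns) of a rank-normalized prediction matrix
#' by Euclidean distance between their score columns and Ward.D2 linkage.
#' Only complete-case variants (no missing score in any column) are used.
#'
#' @param matrix A [prediction_matrix()], typically rank-normalized.
#' @param config A [cluster_config()].
#' @return Object of class `predictor_dendrogram`: the `hclust` object plus
#'   the per-node member sets, the complete-case matrix used, and the config.
#' @export
ward_dendrogram <- function(matrix, config = cluster_config()) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  sc <- matrix$scores
  if (ncol(sc) < 2) stop("need at least 2 algorithms to cluster")
  complete <- stats::complete.cases(sc)
  if (sum(complete) < 2) stop("fewer than 2 complete-case variants")
  sc <- sc[complete, , drop = FALSE]
  sc <- sc[, order(colnames(sc)), drop = FALSE]  # deterministic tie-breaking
  hc <- .cluster_once(sc)
  cl <- .clade_ids(hc)
  members <- lapply(cl$sets, function(ix) sort(colnames(sc)[ix]))
  structure(list(hclust = hc, clade_ids = cl$ids, members = members,
                 heights = hc$height, data = sc, config = config),
            class = "predictor_dendrogram")
}

#' @export
print.predictor_dendrogram <- function(x, ...) {
  cat(sprintf("<predictor_dendrogram> %d algorithms, %d variants (complete case)\n",
              ncol(x$data), nrow(x$data)))
  if (!is.null(x$au))
    cat(sprintf("  AU computed (%d scales x %d replicates)\n",
                length(x$config$scales), x$config$n_boot_per_scale))
  invisible(x)
}

#' @export
plot.predictor_dendrogram <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", ...)
  if (!is.null(x$au)) {
    # annotate internal nodes with AU (percent)
    n <- length(x$hclust$labels)
    xpos <- .node_x(x$hclust)
    graphics::text(xpos, x$hclust$height, labels = round(100 * x$au),
                   col = "red", cex = 0.7, pos = 3)
  }
  invisible(x)
}

.node_x <- function(hc) {
  n <- length(hc$labels)
  leaf_x <- integer(n); leaf_x[hc$order] <- seq_len(n)
  xs <- numeric(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    xs[i] <- mean(vapply(hc$merge[i, ], function(j) {
      if (j < 0) leaf_x[-j] else xs[j]
    }, numeric(1)))
  }
  xs
}

#' Multiscale bootstrap of a predictor dendrogram
#'
#' For each scale factor r, resamples `ceiling(r * n)` variants with
#' replacement `n_boot_per_scale` times, reclusters, and records for each
#' original internal node the proportion of resamples in which its member
#' set reappears as a clade (the bootstrap proportion, BP). Scales for which
#' the resample size falls below 2 are skipped with a warning.
#'
#' @param dendrogram A [ward_dendrogram()] result.
#' @param config A [cluster_config()]; defaults to the one stored in
#'   `dendrogram`.
#' @return The dendrogram with `bp_by_scale` (nodes x scales matrix) and
#'   `scale_sizes` filled in.
#' @export
multiscale_bootstrap <- function(dendrogram, config = NULL) {
  stopifnot(inherits(dendrogram, "predictor_dendrogram"))
  if (is.null(config)) config <- dendrogram$config
  sc <- dendrogram$data
  n <- nrow(sc)
  orig_ids <- dendrogram$clade_ids
  scales <- config$scales
  sizes <- ceiling(scales * n)
  usable <- sizes >= 2
  if (any(!usable))
    warning("skipping scale(s) with resample size < 2: ",
            paste(scales[!usable], collapse = ", "))
  bp <- matrix(NA_real_, length(orig_ids), length(scales),
               dimnames = list(orig_ids, paste0("r", scales)))
  set.seed(config$seed)
  for (si in which(usable)) {
    counts <- integer(length(orig_ids))
    for (b in seq_len(config$n_boot_per_scale)) {
      idx <- sample.int(n, sizes[si], replace = TRUE)
      hb <- .cluster_once(sc[idx, , drop = FALSE])
      ids_b <- .clade_ids(hb)$ids
      counts <- counts + (orig_ids %in% ids_b)
    }
    bp[, si] <- counts / config$n_boot_per_scale
  }
  dendrogram$bp_by_scale <- bp
  dendrogram$scale_sizes <- sizes
  dendrogram$config <- config
  dendrogram
}

#' AU p-value from multiscale bootstrap proportions
#'
#' Fits the signed distance / curvature model of the multiscale bootstrap:
#' with z_r = qnorm(1 - bp_r), weighted least squares of
#' z_r = v * sqrt(r) + c / sqrt(r) across scales (weights from the binomial
#' variance of bp_r), giving the approximately unbiased support
#' au = 1 - pnorm(v - c) and the plain bootstrap probability estimate
#' bp = 1 - pnorm(v + c). BPs are clamped to \[1/(B+1), B/(B+1)\] before the
#' probit so the fit stays finite.
#'
#' @param bp_by_scale Named numeric vector of bootstrap proportions, one per
#'   scale; names or `scales` give the r values.
#' @param n_boot_per_scale Replicates per scale (for the weights and
#'   clamping).
#' @param scales Numeric scale factors; defaults to parsing names
#'   (`"r0.5"` etc.).
#' @return List with `au`, `bp`, `v`, `c`, `n_scales`.
#' @export
au_from_bp <- function(bp_by_scale, n_boot_per_scale, scales = NULL) {
  if (is.null(scales)) {
    scales <- as.numeric(sub("^r", "", names(bp_by_scale)))
  }
  ok <- !is.na(bp_by_scale) & is.finite(scales)
  bp <- bp_by_scale[ok]; r <- scales[ok]
  if (length(bp) < 2)
    return(list(au = NA_real_, bp = NA_real_, v = NA_real_, c = NA_real_,
                n_scales = length(bp)))
  # degenerate clades: present (or absent) in every resample at every scale
  # carry no curvature information; the signed-distance fit would split the
  # constant probit between v and c. Report the extreme support directly.
  if (all(bp >= 1))
    return(list(au = 1, bp = 1, v = -Inf, c = 0, n_scales = length(bp)))
  if (all(bp <= 0))
    return(list(au = 0, bp = 0, v = Inf, c = 0, n_scales = length(bp)))
  B <- n_boot_per_scale
  bp_cl <- pmin(pmax(bp, 1 / (B + 1)), B / (B + 1))
  z <- stats::qnorm(1 - bp_cl)
  # binomial delta-method weights: var(z) ~ bp(1-bp) / (B * phi(z)^2)
  w <- B * stats::dnorm(z)^2 / (bp_cl * (1 - bp_cl))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  list(au = unname(1 - stats::pnorm(v - cc)),
       bp = unname(1 - stats::pnorm(v + cc)),
       v = unname(v), c = unname(cc), n_scales = length(bp))
}

#' Compute AU support for every node of a bootstrapped dendrogram
#'
#' @param dendrogram Output of [multiscale_bootstrap()].
#' @return The dendrogram with `au`, `bp` (per internal node) filled in.
#' @export
au_support <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "predictor_dendrogram"),
            !is.null(dendrogram$bp_by_scale))
  scales <- dendrogram$config$scales
  B <- dendrogram$config$n_boot_per_scale
  fits <- apply(dendrogram$bp_by_scale, 1L, function(row)
    au_from_bp(row, B, scales = scales))
  dendrogram$au <- vapply(fits, `[[`, numeric(1), "au")
  dendrogram$bp <- vapply(fits, `[[`, numeric(1), "bp")
  # the root clade is trivially present in every resample
  dendrogram
}

#' Stable clusters at an AU threshold
#'
#' Returns the maximal internal nodes (excluding the root, which trivially
#' contains every algorithm) whose AU support meets the threshold; nested
#' sub-clusters of a reported cluster are suppressed. Deterministic order:
#' by first member name.
#'
#' @param dendrogram A dendrogram with AU computed ([au_support()]).
#' @param au_threshold Defaults to the configured threshold (0.99).
#' @return List of character vectors (member sets); possibly empty.
#' @export
stable_clusters <- function(dendrogram, au_threshold = NULL) {
  stopifnot(inherits(dendrogram, "predictor_dendrogram"),
            !is.null(dendrogram$au))
  if (is.null(au_threshold)) au_threshold <- dendrogram$config$au_threshold
  n_nodes <- length(dendrogram$members)
  hit <- which(!is.na(dendrogram$au) & dendrogram$au >= au_threshold)
  hit <- setdiff(hit, n_nodes)  # drop root
  if (!length(hit)) return(list())
  # keep only maximal member sets
  keep <- hit[!vapply(hit, function(i) {
    any(vapply(setdiff(hit, i), function(j)
      all(dendrogram$members[[i]] %in% dendrogram$members[[j]]), logical(1)))
  }, logical(1))]
  out <- dendrogram$members[keep]
  out[order(vapply(out, `[`, character(1), 1))]
}

#' One-call clustering pipeline
#'
#' [ward_dendrogram()] + [multiscale_bootstrap()] + [au_support()].
#'
#' @inheritParams ward_dendrogram
#' @return A `predictor_dendrogram` with BP and AU filled in.
#' @export
cluster_predictors <- function(matrix, config = cluster_config()) {
  au_support(multiscale_bootstrap(ward_dendrogram(matrix, config)))
}
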