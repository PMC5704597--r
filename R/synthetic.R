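#' Simulation configuration for synthetic prediction matrices
#'
#' Describes a variants x algorithms score matrix with known truth: per
#' algorithm a target AUC and a correlation-block id, a shared within-block
#' latent-factor correlation, MCAR missingness, and a per-gene class
#' composition (gene count, size distribution, and the probability that a
#' gene carries only one class — the lever for type 2 circularity
#' experiments).
#'
#' @param n_benign,n_pathogenic Variant counts per class.
#' @param algorithms Data frame with columns `name`, `target_auc` (in
#'   \[0.5, 1)) and `block` (integer block id; algorithms sharing a block
#'   share a latent factor).
#' @param block_correlation Within-block score correlation rho in \[0, 1).
#' @param missing_rate MCAR cell missingness probability.
#' @param n_genes Number of genes variants are assigned to.
#' @param gene_size_distribution `"uniform"` (equal expected sizes) or
#'   `"skewed"` (power-law-ish sizes, a few large genes).
#' @param gene_imbalance Probability that a gene carries variants of a
#'   single class only.
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_benign = 500L, n_pathogenic = 500L,
                       algorithms = data.frame(
                         name = paste0("alg", 1:5),
                         target_auc = c(0.9, 0.85, 0.8, 0.75, 0.7),
                         block = c(1L, 1L, 2L, 2L, 3L)),
                       block_correlation = 0.5,
                       missing_rate = 0,
                       n_genes = 50L,
                       gene_size_distribution = c("uniform", "skewed"),
                       gene_imbalance = 0,
                       seed = 1L) {
  gene_size_distribution <- match.arg(gene_size_distribution)
  problems <- character(0)
  if (n_benign < 1 || n_pathogenic < 1)
    problems <- c(problems, "need at least one variant per class")
  if (!all(c("name", "target_auc", "block") %in% names(algorithms)) ||
      nrow(algorithms) < 1)
    problems <- c(problems, "algorithms needs columns name, target_auc, block and >= 1 row")
  else if (any(algorithms$target_auc < 0.5 | algorithms$target_auc >= 1))
    problems <- c(problems, "target_auc must lie in [0.5, 1)")
  if (block_correlation < 0 || block_correlation >= 1)
    problems <- c(problems, "block_correlation must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate > 1)
    problems <- c(problems, "missing_rate must lie in [0, 1]")
  if (gene_imbalance < 0 || gene_imbalance > 1)
    problems <- c(problems, "gene_imbalance must lie in [0, 1]")
  if (n_genes < 1) problems <- c(problems, "need at least one gene")
  if (length(problems))
    stop("invalid sim_config: ", paste(problems, collapse = "; "))
  structure(list(n_benign = as.integer(n_benign),
                 n_pathogenic = as.integer(n_pathogenic),
                 algorithms = algorithms,
                 block_correlation = block_correlation,
                 missing_rate = missing_rate,
                 n_genes = as.integer(n_genes),
                 gene_size_distribution = gene_size_distribution,
                 gene_imbalance = gene_imbalance,
                 seed = seed),
            class = "sim_config")
}

#' The binormal class separation giving a target AUC
#'
#' In the equal-variance binormal model (both classes unit-variance normal,
#' pathogenic mean shifted by mu), AUC = Phi(mu / sqrt(2)); hence
#' mu = sqrt(2) * qnorm(AUC).
#'
#' @param target_auc AUC in \[0.5, 1).
#' @return The mean shift mu.
#' @export
binormal_shift <- function(target_auc) sqrt(2) * stats::qnorm(target_auc)

#' Simulate a prediction matrix with known truth
#'
#' Scores follow a latent-factor binormal model: for algorithm a in block g,
#' `s = sqrt(rho) * F_g + sqrt(1 - rho) * eps + mu_a * [pathogenic]` with
#' `F_g`, `eps` standard normal, so each score has unit variance, algorithms
#' within a block correlate at rho, and `mu_a = sqrt(2) * qnorm(target_auc)`
#' yields the target AUC exactly in expectation. Variants are assigned to
#' genes per the configured size distribution; a gene flagged imbalanced
#' (probability `gene_imbalance`) receives variants of a single class only.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (a [prediction_matrix()] with gene
#'   assignments; all scores higher = more damaging) and `params` (the
#'   generating mu values and config).
#' @export
simulate_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nb <- config$n_benign; np <- config$n_pathogenic
  n <- nb + np
  truth <- c(rep("benign", nb), rep("pathogenic", np))
  alg <- config$algorithms
  rho <- config$block_correlation
  mu <- binormal_shift(alg$target_auc)

  blocks <- unique(alg$block)
  Fg <- matrix(stats::rnorm(n * length(blocks)), n, length(blocks),
               dimnames = list(NULL, as.character(blocks)))
  sc <- matrix(NA_real_, n, nrow(alg),
               dimnames = list(sprintf("v%05d", seq_len(n)), alg$name))
  for (j in seq_len(nrow(alg))) {
    eps <- stats::rnorm(n)
    sc[, j] <- sqrt(rho) * Fg[, as.character(alg$block[j])] +
      sqrt(1 - rho) * eps + mu[j] * (truth == "pathogenic")
  }

  gene <- .assign_genes(truth, config)

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(sc)) < config$missing_rate,
                   nrow(sc), ncol(sc))
    sc[miss] <- NA_real_
  }

  list(matrix = prediction_matrix(sc, truth, gene = gene),
       params = list(mu = stats::setNames(mu, alg$name), config = config))
}

# Assign variants to genes honoring gene_size_distribution and
# gene_imbalance. Imbalanced genes draw from a single class pool; remaining
# variants go to mixed genes proportionally.
.assign_genes <- function(truth, config) {
  n <- length(truth)
  G <- config$n_genes
  w <- switch(config$gene_size_distribution,
              uniform = rep(1, G),
              skewed = 1 / seq_len(G))  # Zipf-like expected sizes
  w <- w / sum(w)
  imbalanced <- stats::runif(G) < config$gene_imbalance
  single_class <- ifelse(stats::runif(G) < 0.5, "benign", "pathogenic")
  gene <- character(n)
  pool <- list(benign = which(truth == "benign"),
               pathogenic = which(truth == "pathogenic"))
  # expected gene sizes, largest remainder rounding
  sizes <- floor(w * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(w * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  for (g in seq_len(G)) {
    take <- sizes[g]
    if (take == 0) next
    if (imbalanced[g]) {
      cls <- single_class[g]
      other <- setdiff(c("benign", "pathogenic"), cls)
      k <- min(take, length(pool[[cls]]))
      pick <- if (k > 0) pool[[cls]][seq_len(k)] else integer(0)
      pool[[cls]] <- setdiff(pool[[cls]], pick)
      # if its class pool ran dry, spill into the other class
      if (k < take) {
        k2 <- min(take - k, length(pool[[other]]))
        pick2 <- pool[[other]][seq_len(k2)]
        pool[[other]] <- setdiff(pool[[other]], pick2)
        pick <- c(pick, pick2)
      }
    } else {
      avail <- c(pool$benign, pool$pathogenic)
      k <- min(take, length(avail))
      pick <- sample(avail, k)
      pool$benign <- setdiff(pool$benign, pick)
      pool$pathogenic <- setdiff(pool$pathogenic, pick)
    }
    gene[pick] <- sprintf("GENE%03d", g)
  }
  leftover <- which(gene == "")
  if (length(leftover)) gene[leftover] <- sprintf("GENE%03d", G)
  gene
}

#' Apply MCAR missingness to a prediction matrix
#'
#' Each score cell is independently set to missing with the given
#' probability.
#'
#' @param matrix A [prediction_matrix()].
#' @param rate Missingness probability in \[0, 1\].
#' @param seed RNG seed.
#' @return A [prediction_matrix()].
#' @export
apply_missingness <- function(matrix, rate, seed = 1L) {
  stopifnot(inherits(matrix, "prediction_matrix"), rate >= 0, rate <= 1)
  if (rate == 0) return(matrix)
  set.seed(seed)
  sc <- matrix$scores
  miss <- matrix(stats::runif(length(sc)) < rate, nrow(sc), ncol(sc))
  sc[miss] <- NA_real_
  prediction_matrix(sc, matrix$truth, gene = matrix$gene,
                    labels = matrix$labels)
}

#' The gene-composition "predictor" (type 2 circularity probe)
#'
#' Scores each variant by the pathogenic fraction of the (other, if
#' `leave_one_out`) variants in its gene — a predictor that knows nothing
#' about the variant itself, only the class composition of its gene. High
#' AUC on an unbalanced cohort and a collapse on a per-gene balanced subset
#' of the same data is the signature of type 2 circularity.
#'
#' @param matrix A [prediction_matrix()] with gene assignments.
#' @param leave_one_out Exclude the variant itself from its gene's fraction
#'   (default TRUE).
#' @param prior Score for variants with no (other) variant in their gene
#'   (default 0.5).
#' @return Numeric score vector named by variant key.
#' @export
gene_composition_predictor <- function(matrix, leave_one_out = TRUE,
                                       prior = 0.5) {
  stopifnot(inherits(matrix, "prediction_matrix"), !is.null(matrix$gene))
  g <- matrix$gene
  y <- as.integer(matrix$truth == "pathogenic")
  n_g <- tapply(y, g, length)
  p_g <- tapply(y, g, sum)
  n_i <- n_g[g]; p_i <- p_g[g]
  if (leave_one_out) {
    denom <- n_i - 1L
    num <- p_i - y
  } else {
    denom <- n_i
    num <- p_i
  }
  out <- ifelse(denom > 0, num / denom, prior)
  stats::setNames(as.numeric(out), rownames(matrix$scores))
}
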