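# Fixture builders and independent oracles shared across test files.

# call matrix from a character matrix written row-wise, e.g.
# make_calls(c("D","T", "T","T"), truth = c("benign","pathogenic"), n_alg = 2)
make_calls <- function(cells, truth, n_alg, gene = NULL) {
  lut <- c(D = "damaging", T = "tolerated", "." = NA_character_)
  m <- matrix(lut[cells], nrow = length(truth), ncol = n_alg, byrow = TRUE,
              dimnames = list(paste0("v", seq_along(truth)),
                              paste0("alg", seq_len(n_alg))))
  call_matrix(m, truth, gene = gene)
}

random_call_matrix <- function(n_var, n_alg, miss = 0.15) {
  m <- matrix(sample(c(0L, 1L), n_var * n_alg, replace = TRUE), n_var, n_alg,
              dimnames = list(paste0("v", seq_len(n_var)),
                              paste0("alg", seq_len(n_alg))))
  m[matrix(stats::runif(n_var * n_alg) < miss, n_var, n_alg)] <- NA_integer_
  call_matrix(m, sample(c("benign", "pathogenic"), n_var, replace = TRUE))
}

# naive per-variant oracle for combination concordance: explicit loop,
# independent of the vectorized engine
naive_concordance <- function(calls, combination, truth_class, missing_policy) {
  m <- calls$calls[, combination, drop = FALSE]
  tr <- calls$truth
  if (truth_class != "all") {
    m <- m[tr == truth_class, , drop = FALSE]
    tr <- tr[tr == truth_class]
  }
  n_eval <- n_true <- n_false <- 0L
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    obs <- v[!is.na(v)]
    evaluable <- if (missing_policy == "complete")
      length(obs) == ncol(m) else length(obs) >= 2L
    if (!evaluable) next
    n_eval <- n_eval + 1L
    if (length(unique(obs)) == 1L) {
      call_dam <- obs[1] == 1L
      truth_dam <- tr[i] == "pathogenic"
      if (call_dam == truth_dam) n_true <- n_true + 1L else n_false <- n_false + 1L
    }
  }
  c(n_evaluable = n_eval, n_true = n_true, n_false = n_false,
    n_discordant = n_eval - n_true - n_false)
}

# brute-force pairwise AUC oracle
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

numeric_spec <- function(name = "num", direction = "higher_damaging",
                         threshold = 0.5) {
  algorithm_spec(name, kind = "numeric", direction = direction,
                 threshold = threshold)
}

# tiny ClinVar-style variant_summary fixture
write_clinvar_fixture <- function(path, rows) {
  header <- paste(c("Name", "GeneSymbol", "ClinicalSignificance",
                    "ReviewStatus", "Assembly", "Chromosome", "Start",
                    "ReferenceAllele", "AlternateAllele"), collapse = "\t")
  writeLines(c(header, rows), path)
}

clinvar_row <- function(name = "NM_000.1(GENE1):c.1A>G (p.Met1Val)",
                        gene = "GENE1", sig = "Pathogenic",
                        status = "criteria provided, single submitter",
                        assembly = "GRCh37", chr = "1", pos = "1000",
                        ref = "A", alt = "G") {
  paste(name, gene, sig, status, assembly, chr, pos, ref, alt, sep = "\t")
}
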