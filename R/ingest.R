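#' Collapse a clinical-significance string to a two-class label
#'
#' "Pathogenic" and "Likely pathogenic" collapse to `"pathogenic"`; "Benign"
#' and "Likely benign" to `"benign"`; anything else (uncertain significance,
#' conflicting interpretations, drug response, ...) to `"other"`. Matching is
#' case-insensitive and total.
#'
#' @param raw Character vector of raw significance strings.
#' @return Character vector of `"benign"`, `"pathogenic"` or `"other"`.
#' @export
collapse_significance <- function(raw) {
  x <- tolower(trimws(as.character(raw)))
  out <- rep("other", length(x))
  out[x %in% c("pathogenic", "likely pathogenic")] <- "pathogenic"
  out[x %in% c("benign", "likely benign")] <- "benign"
  out
}

# ClinVar review-status text -> star tier. Conflicting interpretations keep
# their 1 star here; such records drop out later because their collapsed
# class is 'other'.
.star_map <- c(
  "practice guideline" = 4L,
  "reviewed by expert panel" = 3L,
  "criteria provided, multiple submitters, no conflicts" = 2L,
  "criteria provided, single submitter" = 1L,
  "criteria provided, conflicting interpretations" = 1L,
  "no assertion criteria provided" = 0L,
  "no interpretation for the single variant" = 0L,
  "no assertion provided" = 0L
)

#' Map ClinVar review-status text to star tiers
#'
#' Standard ClinVar semantics: practice guideline = 4, expert panel = 3,
#' multiple concordant submitters = 2, single submitter (or conflicting
#' interpretations) = 1, no assertion criteria = 0. Unrecognized text maps
#' to 0 with a warning.
#'
#' @param status Character vector of review-status strings.
#' @return Integer vector of stars in 0..4.
#' @export
review_stars <- function(status) {
  x <- tolower(trimws(as.character(status)))
  stars <- unname(.star_map[x])
  unknown <- is.na(stars) & !is.na(x)
  if (any(unknown)) {
    warning(sum(unknown), " unrecognized review status value(s) mapped to 0 stars: ",
            paste(utils::head(unique(x[unknown]), 3), collapse = "; "))
    stars[unknown] <- 0L
  }
  stars
}

# Missense from an HGVS protein change: p.Xaa123Yaa with distinct three-letter
# residues, excluding Ter/fs/del/dup/ins events.
.aa3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile","Leu",
          "Lys","Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val")

.is_missense_p <- function(p) {
  if (length(p) == 0) return(logical(0))
  pat <- sprintf("p\\.(%s)(\\d+)(%s)", paste(.aa3, collapse = "|"),
                 paste(.aa3, collapse = "|"))
  m <- regmatches(p, regexec(pat, p))
  vapply(seq_along(p), function(i) {
    mi <- m[[i]]
    if (length(mi) != 4L) return(FALSE)
    if (grepl("Ter|fs|del|dup|ins|ext", p[i])) return(FALSE)
    mi[2] != mi[4]
  }, logical(1))
}

#' Read a ClinVar-style variant summary table
#'
#' Reads a tab-delimited `variant_summary.txt`-dialect file, keeps rows for
#' the requested assembly, derives the collapsed two-class label and review
#' stars, and collapses duplicate variant keys (first occurrence wins; the
#' number dropped is recorded in `attr(, "n_duplicates")` and warned about).
#'
#' Required columns (ClinVar headers): `Name`, `GeneSymbol`,
#' `ClinicalSignificance`, `ReviewStatus`, `Assembly`, `Chromosome`, `Start`,
#' `ReferenceAllele`, `AlternateAllele`. A `MolecularConsequence` column is
#' used for missense detection when present; otherwise the HGVS p. part of
#' `Name` is parsed.
#'
#' @param path Tab-delimited file with a header row.
#' @param assembly Assembly to keep (e.g. `"GRCh37"`).
#' @param snapshot Optional snapshot label stored as `first_seen`.
#' @return A data frame of variant records, one per variant key:
#'   `key`, `gene_symbol`, `protein_change`, `raw_significance`, `clin_class`,
#'   `review_stars`, `consequence`, `first_seen` plus the coordinate columns.
#' @export
read_clinvar_summary <- function(path, assembly, snapshot = NA_character_) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "")
  names(df) <- sub("^#", "", names(df))
  required <- c("Name", "GeneSymbol", "ClinicalSignificance", "ReviewStatus",
                "Assembly", "Chromosome", "Start", "ReferenceAllele",
                "AlternateAllele")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[df$Assembly == assembly, , drop = FALSE]

  protein_change <- vapply(df$Name, function(nm) {
    m <- regmatches(nm, regexpr("p\\.[A-Za-z0-9*=]+", nm))
    if (length(m)) m else ""
  }, character(1), USE.NAMES = FALSE)

  consequence <- if ("MolecularConsequence" %in% names(df)) {
    ifelse(grepl("missense", df$MolecularConsequence, ignore.case = TRUE),
           "missense", df$MolecularConsequence)
  } else {
    ifelse(.is_missense_p(protein_change), "missense", "")
  }

  rec <- data.frame(
    key = paste(assembly, df$Chromosome, df$Start, df$ReferenceAllele,
                df$AlternateAllele, sep = ":"),
    assembly = assembly,
    chromosome = df$Chromosome,
    position = as.integer(df$Start),
    ref = df$ReferenceAllele,
    alt = df$AlternateAllele,
    gene_symbol = df$GeneSymbol,
    protein_change = protein_change,
    raw_significance = df$ClinicalSignificance,
    clin_class = collapse_significance(df$ClinicalSignificance),
    review_stars = review_stars(df$ReviewStatus),
    consequence = consequence,
    first_seen = snapshot,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(rec$key)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warning(n_dup, " duplicate variant key(s) collapsed (first occurrence kept)")
    rec <- rec[!dup, , drop = FALSE]
  }
  rownames(rec) <- NULL
  attr(rec, "n_duplicates") <- n_dup
  rec
}

#' Apply the inclusion filters to parsed variant records
#'
#' Keeps records with at least `min_stars` review stars and a collapsed class
#' of benign or pathogenic; optionally restricts to missense consequences and
#' optionally drops "Likely" assertions (for the definite-only cohort).
#' Idempotent.
#'
#' @param records Data frame from [read_clinvar_summary()].
#' @param min_stars Minimum review stars (default 1, i.e. assertion criteria
#'   provided).
#' @param missense_only Keep only missense records.
#' @param exclude_likely Additionally drop records whose raw significance
#'   contains "Likely".
#' @return Filtered data frame.
#' @export
filter_variants <- function(records, min_stars = 1L, missense_only = TRUE,
                            exclude_likely = FALSE) {
  keep <- records$review_stars >= min_stars &
    records$clin_class %in% c("benign", "pathogenic")
  if (missense_only) keep <- keep & records$consequence == "missense"
  if (exclude_likely)
    keep <- keep & !grepl("likely", records$raw_significance, ignore.case = TRUE)
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no variants remain after filtering")
  rownames(out) <- NULL
  out
}

#' Read a dbNSFP-style score table into a prediction matrix
#'
#' The table is keyed by `chr`, `pos`, `ref`, `alt` with one column per
#' algorithm. Multi-transcript cells (`;`-separated) are reduced to the most
#' damaging value per [most_damaging()]; `.` or empty tokens are missing.
#' Truth labels are joined from `truth_source` (benign/pathogenic records
#' only); variants without a truth label are dropped and their count logged
#' in `attr(, "n_dropped_no_truth")`.
#'
#' @param path Tab-delimited score table.
#' @param specs Named list of [algorithm_spec()]s; every spec name must be a
#'   column.
#' @param truth_source Data frame of variant records carrying `key`,
#'   `clin_class` and `gene_symbol` (e.g. from [filter_variants()]).
#' @param assembly Assembly string used to form keys matching `truth_source`.
#' @return A [prediction_matrix()].
#' @export
read_score_table <- function(path, specs, truth_source, assembly = "GRCh37") {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "")
  names(df) <- sub("^#", "", names(df))
  key_cols <- c("chr", "pos", "ref", "alt")
  miss <- setdiff(key_cols, names(df))
  if (length(miss)) stop("missing key column(s): ", paste(miss, collapse = ", "))
  alg <- names(specs)
  absent <- setdiff(alg, names(df))
  if (length(absent))
    stop("algorithm column(s) absent from score table: ",
         paste(absent, collapse = ", "))

  key <- paste(assembly, df$chr, df$pos, df$ref, df$alt, sep = ":")
  n_warn <- 0L
  num_alg <- alg[vapply(specs[alg], function(s) s$kind == "numeric", logical(1))]
  cat_alg <- setdiff(alg, num_alg)
  sc <- matrix(NA_real_, nrow(df), length(num_alg),
               dimnames = list(key, num_alg))
  for (a in num_alg) {
    spec <- specs[[a]]
    cells <- strsplit(df[[a]], ";", fixed = TRUE)
    sc[, a] <- vapply(cells, function(vals) {
      vals <- vals[!(vals %in% c(".", ""))]
      if (!length(vals)) return(NA_real_)
      num <- suppressWarnings(as.numeric(vals))
      if (anyNA(num)) {
        n_warn <<- n_warn + sum(is.na(num))
        num <- num[!is.na(num)]
        if (!length(num)) return(NA_real_)
      }
      most_damaging(num, spec)
    }, numeric(1))
  }
  if (n_warn > 0)
    warning(n_warn, " non-numeric score token(s) treated as missing")
  labels <- NULL
  if (length(cat_alg)) {
    labels <- matrix(NA_character_, nrow(df), length(cat_alg),
                     dimnames = list(key, cat_alg))
    for (a in cat_alg) {
      cmap <- specs[[a]]$categorical_map
      cells <- strsplit(df[[a]], ";", fixed = TRUE)
      labels[, a] <- vapply(cells, function(vals) {
        vals <- vals[!(vals %in% c(".", ""))]
        if (!length(vals)) return(NA_character_)
        # most damaging label: damaging beats tolerated beats unknown/NA
        sev <- ifelse(is.na(cmap[vals]), 0L,
                      ifelse(cmap[vals] == "damaging", 2L, 1L))
        vals[which.max(sev)]
      }, character(1))
    }
  }

  ts <- truth_source[truth_source$clin_class %in% c("benign", "pathogenic"), ]
  idx <- match(key, ts$key)
  drop <- is.na(idx)
  n_drop <- sum(drop)
  sc <- sc[!drop, , drop = FALSE]
  if (!is.null(labels)) labels <- labels[!drop, , drop = FALSE]
  idx <- idx[!drop]
  out <- prediction_matrix(sc, ts$clin_class[idx], gene = ts$gene_symbol[idx],
                           labels = labels)
  attr(out, "n_dropped_no_truth") <- n_drop
  out
}
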