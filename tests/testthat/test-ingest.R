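test_that("significance collapsing is total and case-insensitive", {
  expect_equal(collapse_significance("Likely pathogenic"), "pathogenic")
  expect_equal(collapse_significance("PATHOGENIC"), "pathogenic")
  expect_equal(collapse_significance("Benign"), "benign")
  expect_equal(collapse_significance("likely benign"), "benign")
  expect_equal(collapse_significance("Uncertain significance"), "other")
  expect_equal(collapse_significance("Conflicting interpretations of pathogenicity"),
               "other")
  expect_equal(collapse_significance(""), "other")
  # partition property: every input lands in exactly one of the three classes
  inputs <- c("Pathogenic", "Benign", "Likely benign", "risk factor", "VUS",
              "drug response", "Likely pathogenic", "other")
  cls <- collapse_significance(inputs)
  expect_true(all(cls %in% c("benign", "pathogenic", "other")))
  expect_length(cls, length(inputs))
})

test_that("review-status text maps to the standard star tiers", {
  expect_equal(review_stars("practice guideline"), 4L)
  expect_equal(review_stars("reviewed by expert panel"), 3L)
  expect_equal(review_stars("criteria provided, multiple submitters, no conflicts"), 2L)
  expect_equal(review_stars("criteria provided, single submitter"), 1L)
  expect_equal(review_stars("criteria provided, conflicting interpretations"), 1L)
  expect_equal(review_stars("no assertion criteria provided"), 0L)
  expect_warning(s <- review_stars("some future status"), "unrecognized")
  expect_equal(s, 0L)
})

test_that("clinvar reader filters assembly, dedups keys, parses p. notation", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_clinvar_fixture(tmp, c(
    clinvar_row(pos = "100"),
    clinvar_row(pos = "200", sig = "Benign",
                name = "NM_000.1(GENE1):c.2C>T (p.Ala2Val)"),
    clinvar_row(pos = "300", assembly = "GRCh38"),
    clinvar_row(pos = "100")  # duplicate key
  ))
  expect_warning(rec <- read_clinvar_summary(tmp, "GRCh37"), "duplicate")
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "n_duplicates"), 1L)
  expect_setequal(rec$clin_class, c("pathogenic", "benign"))
  expect_equal(rec$protein_change[1], "p.Met1Val")
  expect_true(all(rec$consequence == "missense"))
  expect_true(all(grepl("^GRCh37:", rec$key)))
})

test_that("missing required columns are a fatal, named error", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Name\tGeneSymbol", "x\ty"), tmp)
  expect_error(read_clinvar_summary(tmp, "GRCh37"), "ClinicalSignificance")
})

test_that("missense detection by HGVS p. excludes non-missense events", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_clinvar_fixture(tmp, c(
    clinvar_row(pos = "1", name = "x (p.Arg97Gly)"),
    clinvar_row(pos = "2", name = "x (p.Arg97Ter)"),
    clinvar_row(pos = "3", name = "x (p.Ala4fs)"),
    clinvar_row(pos = "4", name = "x (p.Met5Met)"),   # synonymous
    clinvar_row(pos = "5", name = "x (c.10del)")
  ))
  rec <- read_clinvar_summary(tmp, "GRCh37")
  expect_equal(rec$consequence == "missense", c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("filter_variants applies stars/class/missense/likely rules and is idempotent", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_clinvar_fixture(tmp, c(
    clinvar_row(pos = "1"),
    clinvar_row(pos = "2", status = "no assertion criteria provided"),
    clinvar_row(pos = "3", sig = "Uncertain significance"),
    clinvar_row(pos = "4", name = "x (p.Ala4fs)"),
    clinvar_row(pos = "5", sig = "Likely benign",
                name = "x (p.Ala4Gly)")
  ))
  rec <- read_clinvar_summary(tmp, "GRCh37")
  f <- filter_variants(rec, min_stars = 1L, missense_only = TRUE)
  expect_equal(sort(f$position), c(1L, 5L))
  # class partition accounting over the parsed records
  expect_equal(sum(rec$clin_class == "benign") + sum(rec$clin_class == "pathogenic") +
                 sum(rec$clin_class == "other"), nrow(rec))
  # idempotent
  expect_identical(filter_variants(f, 1L, TRUE), f)
  # exclude_likely drops the Likely benign record
  f2 <- filter_variants(rec, 1L, TRUE, exclude_likely = TRUE)
  expect_equal(f2$position, 1L)
})

test_that("score table reader reduces transcripts, handles missing, joins truth", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chr\tpos\tref\talt\tsiftlike\thigherlike",
    "1\t100\tA\tG\t0.12;0.03\t0.2;0.9",
    "1\t200\tC\tT\t.\t0.5",
    "1\t300\tG\tA\t0.5\t0.1"
  ), tmp)
  specs <- list(
    siftlike = numeric_spec("siftlike", "lower_damaging", 0.05),
    higherlike = numeric_spec("higherlike", "higher_damaging", 0.5)
  )
  truth <- data.frame(
    key = c("GRCh37:1:100:A:G", "GRCh37:1:200:C:T"),
    clin_class = c("pathogenic", "benign"),
    gene_symbol = c("G1", "G2"), stringsAsFactors = FALSE)
  pm <- read_score_table(tmp, specs, truth)
  expect_equal(nrow(pm$scores), 2L)           # v300 has no truth -> dropped
  expect_equal(attr(pm, "n_dropped_no_truth"), 1L)
  expect_equal(pm$scores["GRCh37:1:100:A:G", "siftlike"], 0.03)  # min rule
  expect_equal(pm$scores["GRCh37:1:100:A:G", "higherlike"], 0.9) # max rule
  expect_true(is.na(pm$scores["GRCh37:1:200:C:T", "siftlike"]))
  # absent algorithm column is fatal
  specs$gone <- numeric_spec("gone")
  expect_error(read_score_table(tmp, specs, truth), "gone")
})

test_that("prediction matrix TSV round-trip is exact", {
  set.seed(11)
  sc <- matrix(rnorm(20), 5, 4,
               dimnames = list(paste0("v", 1:5), paste0("a", 1:4)))
  sc[2, 3] <- NA
  labels <- matrix(c("D", "T", NA, "D", "B"), 5, 1,
                   dimnames = list(paste0("v", 1:5), "catalg"))
  pm <- prediction_matrix(sc, c("benign", "benign", "pathogenic",
                                "pathogenic", "benign"),
                          gene = paste0("G", c(1, 1, 2, 2, 3)),
                          labels = labels)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_matrix(pm, tmp)
  back <- read_prediction_matrix(tmp)
  expect_identical(back$scores, pm$scores)
  expect_identical(back$truth, pm$truth)
  expect_identical(back$gene, pm$gene)
  expect_identical(back$labels, pm$labels)
})
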