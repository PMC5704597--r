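polyphen_spec <- algorithm_spec("Polyphen", kind = "categorical",
  categorical_map = c(D = "damaging", P = "damaging", B = "tolerated",
                      "probably damaging" = "damaging",
                      "possibly damaging" = "damaging",
                      "benign" = "tolerated"))
lrt_spec <- algorithm_spec("LRT", kind = "categorical",
  categorical_map = c(D = "damaging", N = "tolerated", U = NA))
mt_spec <- algorithm_spec("MutationTaster", kind = "categorical",
  categorical_map = c(A = "damaging", D = "damaging",
                      N = "tolerated", P = "tolerated"))

test_that("categorical labels collapse per the per-algorithm maps", {
  expect_equal(map_categorical("possibly damaging", polyphen_spec), "damaging")
  expect_equal(map_categorical("probably damaging", polyphen_spec), "damaging")
  expect_equal(map_categorical(c("N", "P"), mt_spec),
               c("tolerated", "tolerated"))
  expect_equal(map_categorical(c("A", "D"), mt_spec),
               c("damaging", "damaging"))
  expect_true(is.na(map_categorical("U", lrt_spec)))          # Unknown -> no data
  expect_warning(out <- map_categorical("Zebra", lrt_spec), "unknown")
  expect_true(is.na(out))
})

test_that("threshold binarization is direction-aware and damaging-inclusive", {
  sift <- numeric_spec("sift", "lower_damaging", 0.05)
  cadd <- numeric_spec("cadd", "higher_damaging", 15)
  expect_equal(binarize_score(0.049, sift), "damaging")
  expect_equal(binarize_score(0.05, sift), "damaging")    # inclusive boundary
  expect_equal(binarize_score(0.051, sift), "tolerated")
  expect_equal(binarize_score(c(15, 14.9, 20), cadd),
               c("damaging", "tolerated", "damaging"))
  expect_true(is.na(binarize_score(NA, sift)))
  expect_warning(out <- binarize_score(Inf, sift), "non-finite")
  expect_true(is.na(out))
})

test_that("binarization is monotone in the damaging direction", {
  spec <- numeric_spec("m", "higher_damaging", 0.3)
  s <- sort(runif(50))
  calls <- binarize_score(s, spec)
  # once damaging, always damaging for larger scores
  expect_true(all(diff(calls == "damaging") >= 0))
})

test_that("most_damaging picks the extreme on the damaging side", {
  lower <- numeric_spec("l", "lower_damaging", 0)
  higher <- numeric_spec("h", "higher_damaging", 0)
  expect_equal(most_damaging(c(0.12, 0.03, NA), lower), 0.03)
  expect_equal(most_damaging(c(0.2, 0.9), higher), 0.9)
  expect_true(is.na(most_damaging(c(NA_real_, NA_real_), lower)))
})

test_that("build_call_matrix binarizes element-wise and drops no-threshold columns", {
  sc <- matrix(c(0.1, 0.9, 0.4, 0.6,   # alg A (>= 0.5 damaging)
                 1, 2, 3, 4),          # conservation score, no threshold
               ncol = 2, dimnames = list(paste0("v", 1:4), c("A", "cons")))
  labels <- matrix(c("D", "B", NA, "P"), ncol = 1,
                   dimnames = list(paste0("v", 1:4), "Polyphen"))
  pm <- prediction_matrix(sc, rep(c("benign", "pathogenic"), 2),
                          labels = labels)
  specs <- list(
    A = numeric_spec("A", "higher_damaging", 0.5),
    cons = algorithm_spec("cons", kind = "numeric",
                          direction = "higher_damaging",
                          family = "conservation",
                          has_public_threshold = FALSE),
    Polyphen = polyphen_spec)
  expect_message(cm <- build_call_matrix(pm, specs), "cons")
  expect_setequal(colnames(cm$calls), c("A", "Polyphen"))
  expect_equal(attr(cm, "excluded"), "cons")
  expect_equal(unname(cm$calls[, "A"]), c(0L, 1L, 0L, 1L))
  expect_equal(unname(cm$calls[, "Polyphen"]), c(1L, 0L, NA, 1L))
})

test_that("build_call_matrix commutes with variant permutation", {
  set.seed(3)
  sc <- matrix(runif(30), 10, 3,
               dimnames = list(paste0("v", 1:10), c("a", "b", "c")))
  pm <- prediction_matrix(sc, sample(c("benign", "pathogenic"), 10, TRUE))
  specs <- lapply(setNames(nm = c("a", "b", "c")), function(n)
    numeric_spec(n, "higher_damaging", 0.5))
  cm <- build_call_matrix(pm, specs)
  perm <- sample(10)
  pm2 <- prediction_matrix(sc[perm, ], pm$truth[perm])
  cm2 <- build_call_matrix(pm2, specs)
  expect_identical(cm2$calls, cm$calls[perm, ])
})

test_that("rank normalization aligns direction and uses average fractional ranks", {
  sc <- cbind(up = c(1, 2, 3), down = c(0.01, 0.5, NA))
  dimnames(sc) <- list(paste0("v", 1:3), c("up", "down"))
  pm <- prediction_matrix(sc, c("benign", "benign", "pathogenic"))
  specs <- list(up = numeric_spec("up", "higher_damaging", 0),
                down = numeric_spec("down", "lower_damaging", 0))
  rn <- rank_normalize(pm, specs)
  expect_equal(unname(rn$scores[, "up"]), c(1/3, 2/3, 1))
  # lower_damaging: smallest raw score becomes the top rank
  expect_equal(unname(rn$scores[, "down"]), c(1, 0.5, NA))
  # ties get the average fractional rank
  sc2 <- cbind(t = c(5, 5))
  dimnames(sc2) <- list(c("v1", "v2"), "t")
  pm2 <- prediction_matrix(sc2, c("benign", "pathogenic"))
  expect_warning(rn2 <- rank_normalize(pm2), "constant")
  expect_equal(unname(rn2$scores[, "t"]), c(0.75, 0.75))
})

test_that("rank normalization is invariant under strictly increasing transforms", {
  set.seed(9)
  x <- rnorm(40)
  for (f in list(function(v) exp(v), function(v) v^3, function(v) 5 * v - 2)) {
    sc1 <- cbind(a = x); sc2 <- cbind(a = f(x))
    dimnames(sc1) <- dimnames(sc2) <- list(paste0("v", 1:40), "a")
    tr <- rep(c("benign", "pathogenic"), 20)
    expect_equal(rank_normalize(prediction_matrix(sc1, tr))$scores,
                 rank_normalize(prediction_matrix(sc2, tr))$scores)
  }
})

test_that("the shipped registry is readable and covers both kinds", {
  reg <- default_algorithm_registry()
  expect_length(reg, 25L)
  expect_equal(sum(vapply(reg, `[[`, logical(1), "has_public_threshold")), 18L)
  kinds <- vapply(reg, `[[`, character(1), "kind")
  expect_true(all(kinds %in% c("numeric", "categorical")))
  expect_true(any(kinds == "categorical"))
  # numeric entries with a public threshold carry a finite one
  for (s in reg)
    if (s$kind == "numeric" && s$has_public_threshold)
      expect_true(is.finite(s$threshold))
})
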