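test_that("repeated CV produces the full fold/run accounting", {
  ds <- synth_peptides(30, 30, mechanism = "composition", effect = 1.5,
                       seed = 61)
  rep <- repeated_cv(ds, features = "F2", runs = 2, folds = 3, seed = 1,
                     ntree = 40)
  expect_equal(nrow(rep$folds), 6L)
  expect_equal(nrow(rep$runs), 2L)
  expect_true(all(c("SN", "SP", "ACC", "MCC", "AUC") %in% names(rep$runs)))
  expect_true(all(rep$folds$AUC >= 0 & rep$folds$AUC <= 1))
  # identical seed reproduces the report bit for bit
  rep2 <- repeated_cv(ds, features = "F2", runs = 2, folds = 3, seed = 1,
                      ntree = 40)
  expect_identical(rep$folds, rep2$folds)
  # TSV round trip keeps all fold rows
  path <- tempfile(fileext = ".tsv")
  write_cv_report(rep, path)
  back <- read.delim(path, colClasses = c(subset = "character"))
  expect_equal(nrow(back), 6L)
  expect_equal(back$AUC, rep$folds$AUC)
})

test_that("stratified folds balance classes and reject tiny classes", {
  labels <- c(rep(1L, 30), rep(0L, 12))
  f <- stratified_folds(labels, 3, seed = 2)
  for (k in 1:3) {
    expect_equal(sum(labels[f == k] == 1), 10)
    expect_equal(sum(labels[f == k] == 0), 4)
  }
  expect_error(stratified_folds(c(1, 1, 1, 0), 3, seed = 1), "too few")
})

test_that("merged-vector pipeline trains one forest on concatenated blocks", {
  ds <- synth_peptides(24, 24, mechanism = "composition", effect = 1.5,
                       seed = 67)
  rep <- repeated_cv(ds, mode = "merged", features = c("F2", "F8"), runs = 1,
                     folds = 3, seed = 2, ntree = 40)
  expect_equal(nrow(rep$folds), 3L)
  expect_true(all(rep$folds$subset == "11"))
  # concatenated width equals the sum of the blocks' dimensions
  x <- do.call(cbind, encode_features(ds, c("F2", "F8")))
  expect_equal(ncol(x), feature_dim("F2") + feature_dim("F8"))
})

test_that("GA-in-the-loop CV re-selects the subset per fold", {
  ds <- synth_peptides(40, 40, mechanism = "composition", effect = 2,
                       seed = 71)
  rep <- repeated_cv(ds, mode = "ga", features = c("F2", "F9", "F18"),
                     runs = 1, folds = 3, seed = 3, control = tiny_control(),
                     ntree = 40)
  expect_equal(nrow(rep$folds), 3L)
  expect_true(all(nchar(rep$folds$subset) == 3L))
  freq <- subset_frequencies(rep)
  expect_named(freq, c("F2", "F9", "F18"))
  expect_true(all(freq >= 0 & freq <= 3))
  # total selected bits across folds equals the frequency sum
  bits <- sapply(strsplit(rep$folds$subset, ""),
                 function(b) sum(as.integer(b)))
  expect_equal(sum(freq), sum(bits))
  expect_true(all(bits >= 1))
})

test_that("correlation table is symmetric with unit diagonal", {
  set.seed(73)
  m <- cbind(a = runif(10), b = runif(10), c = runif(10))
  m <- cbind(m, dup = m[, "a"])
  ct <- correlation_table(m)
  expect_equal(ct, t(ct))
  expect_equal(unname(diag(ct)), rep(1, 4))
  expect_true(all(ct >= 0 & ct <= 1))
  expect_equal(ct["a", "dup"], 1)
  # hand-computed Pearson r on a 5-point toy pair
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - 3) * (y - 3.2)) /
    sqrt(sum((x - 3)^2) * sum((y - 3.2)^2))
  expect_equal(correlation_table(cbind(x, y, z = c(5, 1, 2, 4, 3)))["x", "y"],
               abs(r_hand))
  expect_warning(ct0 <- correlation_table(cbind(x, const = rep(1, 5))),
                 "zero-variance")
  expect_true(is.na(ct0["x", "const"]))
})

test_that("significance tests handle paired, one-sample and degenerate input", {
  set.seed(79)
  a <- 0.846 + rnorm(20, sd = 1e-3)
  # one-sample test against a far-away published mean is overwhelming
  t1 <- compare_auc(a, mu = 0.64)
  expect_lt(t1$p.value, 1e-10)
  b <- a - 0.05 + rnorm(20, sd = 1e-3)
  t2 <- compare_auc(a, y = b)
  expect_lt(t2$p.value, 0.05)
  # swapping the samples preserves the paired p-value
  t3 <- compare_auc(b, y = a)
  expect_equal(t2$p.value, t3$p.value)
  expect_warning(nd <- compare_auc(a, y = a), "zero-variance")
  expect_true(is.na(nd))
  expect_error(compare_auc(a), "exactly one")
  ref <- reference_auc()
  expect_true(all(c("dataset", "method", "AUC") %in% names(ref)))
})
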