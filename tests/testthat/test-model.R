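test_that("base predictor separates a separable block and is seeded", {
  set.seed(3)
  x <- rbind(matrix(rnorm(200, 3), 20), matrix(rnorm(200, -3), 20))
  y <- rep(c(1L, 0L), each = 20)
  base <- train_base(x, y, seed = 7, ntree = 60)
  expect_equal(roc_auc(predict_base(base, x), y), 1)
  base2 <- train_base(x, y, seed = 7, ntree = 60)
  expect_identical(predict_base(base, x), predict_base(base2, x))
  expect_error(train_base(x, rep(1L, 40), seed = 1), "both classes")
  expect_error(train_base(x, y[1:10], seed = 1))
})

test_that("base predictor finds planted signal on held-out data", {
  ds <- synth_peptides(100, 100, mechanism = "composition", effect = 1.5,
                       seed = 17)
  blocks <- encode_features(ds, "F2")
  tr <- c(1:70, 101:170)
  base <- train_base(blocks$F2[tr, ], ds$label[tr], seed = 5, ntree = 100)
  auc <- roc_auc(predict_base(base, blocks$F2[-tr, ]), ds$label[-tr])
  expect_gt(auc, 0.5)
})

test_that("ensemble score is the mean of base scores and is bounded", {
  ds <- synth_peptides(20, 20, mechanism = "composition", effect = 2,
                       seed = 23)
  fit <- ensemble_fit(ds, c("F2", "F8", "F9"), seed = 3, ntree = 40)
  probe <- random_peptides(10, seed = 55)
  scores <- predict(fit, probe)
  blocks <- encode_features(probe, c("F2", "F8", "F9"), context = fit$context)
  per_base <- sapply(c("F2", "F8", "F9"),
                     function(f) predict_base(fit$bases[[f]], blocks[[f]]))
  expect_equal(scores, rowMeans(per_base))
  expect_true(all(scores >= apply(per_base, 1, min) - 1e-12))
  expect_true(all(scores <= apply(per_base, 1, max) + 1e-12))
  # averaging in a constant-0.5 base shrinks every score toward 0.5
  with_half <- (rowMeans(per_base) * 3 + 0.5) / 4
  expect_true(all(abs(with_half - 0.5) <= abs(scores - 0.5) + 1e-12))
  # single-feature ensemble reduces to its base predictor
  fit1 <- ensemble_fit(ds, "F2", seed = 3, ntree = 40)
  b1 <- encode_features(probe, "F2", context = fit1$context)
  expect_equal(predict(fit1, probe), predict_base(fit1$bases$F2, b1$F2))
})

test_that("classification thresholds follow the tie-positive rule", {
  expect_equal(classify_scores(c(0.2, 0.5, 0.8), 0.5), c(0L, 1L, 1L))
  expect_equal(classify_scores(c(0.2, 0.5, 0.8), 0), c(1L, 1L, 1L))
  expect_error(classify_scores(0.5, 1.1), "threshold")
  expect_error(classify_scores(0.5, -0.1), "threshold")
  ds <- synth_peptides(12, 12, seed = 2)
  fit <- ensemble_fit(ds, "F2", seed = 1, ntree = 30)
  cls <- predict(fit, ds, type = "class", threshold = 0)
  expect_equal(cls, rep(1L, 24))
})

test_that("ensemble training is reproducible under a fixed seed", {
  ds <- synth_peptides(15, 15, mechanism = "property", effect = 1, seed = 29)
  f1 <- ensemble_fit(ds, c("F2", "F13"), seed = 11, ntree = 40)
  f2 <- ensemble_fit(ds, c("F2", "F13"), seed = 11, ntree = 40)
  probe <- random_peptides(8, seed = 101)
  expect_identical(predict(f1, probe), predict(f2, probe))
})
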