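test_that("fitness of planted-signal and pure-noise subsets behaves", {
  # near-separable planted composition signal
  strong <- synth_peptides(100, 100, mechanism = "composition", effect = 4,
                           seed = 37)
  fit_strong <- fitness_eval(c(1L), strong, features = "F2", folds = 5,
                             seed = 1, ntree = 100)
  expect_gte(fit_strong, 0.95)
  # null data: fitness concentrates near 0.5
  null <- synth_peptides(200, 200, effect = 0, seed = 41)
  fit_null <- fitness_eval(c(1L), null, features = "F2", folds = 5,
                           seed = 1, ntree = 100)
  expect_gte(fit_null, 0.4)
  expect_lte(fit_null, 0.6)
  expect_error(fitness_eval(c(0L), null, features = "F2"), "empty")
})

test_that("cached per-feature scores reproduce direct fitness evaluation", {
  ds <- synth_peptides(40, 40, mechanism = "composition", effect = 1.5,
                       seed = 43)
  feats <- c("F2", "F8", "F9")
  oof <- internal_cv_scores(ds, feats, folds = 3, seed = 5, ntree = 40)
  expect_equal(dim(oof$scores), c(80L, 3L))
  expect_false(anyNA(oof$scores))
  # subset fitness from the cache equals recomputing that subset alone
  direct <- fitness_eval(c(1L, 0L, 1L), ds, features = feats, folds = 3,
                         seed = 5, ntree = 40)
  cached <- fitness_from_scores(c(1L, 0L, 1L), oof)
  expect_equal(cached, direct)
})

test_that("evolution keeps the elite and repairs empty chromosomes", {
  set.seed(19)
  ctrl <- ga_control(pop_size = 12, elite = 2, crossover_fraction = 0.6,
                     mutation_rate = 0.2)
  pop <- matrix(rbinom(12 * 6, 1, 0.5), 12, 6)
  pop[rowSums(pop) == 0, 1] <- 1L
  fitness <- runif(12)
  child <- epiGA:::evolve_population(pop, fitness, ctrl)
  expect_equal(dim(child), dim(pop))
  best2 <- pop[order(fitness, decreasing = TRUE)[1:2], ]
  expect_equal(child[1:2, ], best2)
  expect_true(all(rowSums(child) >= 1))
  # mutation 0 + crossover 0 -> non-elite children are copies of parents
  ctrl0 <- ga_control(pop_size = 12, elite = 2, crossover_fraction = 0,
                      mutation_rate = 0)
  child0 <- epiGA:::evolve_population(pop, fitness, ctrl0)
  keys <- apply(pop, 1, paste, collapse = "")
  expect_true(all(apply(child0, 1, paste, collapse = "") %in% keys))
})

test_that("uniform crossover preserves parental allele frequencies", {
  # all-crossover population update on two fixed parents; offspring bit
  # frequency at each locus should match the parental mean (0.5 here)
  ctrl <- ga_control(pop_size = 500, elite = 0, crossover_fraction = 1,
                     mutation_rate = 0)
  pop <- rbind(matrix(1L, 250, 8), matrix(0L, 250, 8))
  pop[, 1] <- 1L  # avoid all-zero repair interference
  set.seed(31)
  child <- epiGA:::evolve_population(pop, rep(1, 500), ctrl)
  freq <- colMeans(child[, -1])
  chi2 <- sum((freq - 0.5)^2 / (0.5 * 0.5 / nrow(child)))
  expect_lt(chi2, qchisq(0.999, df = 7))
})

test_that("GA search is elitist-monotone, seeded, and terminates", {
  ds <- synth_peptides(40, 40, mechanism = "composition", effect = 1.5,
                       seed = 47)
  feats <- c("F2", "F8", "F9", "F18")
  r1 <- ga_select(ds, feats, control = tiny_control(), seed = 3)
  r2 <- ga_select(ds, feats, control = tiny_control(), seed = 3)
  expect_identical(r1$best_bits, r2$best_bits)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$best) >= -1e-12))
  expect_lte(r1$evaluations,
             tiny_control()$pop_size * (max(r1$history$generation) + 1))
  expect_gte(sum(r1$best_bits), 1)
  # one-generation boundary case still yields a valid result
  r3 <- ga_select(ds, feats,
                  control = tiny_control(max_generations = 1), seed = 3)
  expect_equal(max(r3$history$generation), 1L)
  expect_s3_class(r3, "ga_result")
})

test_that("GA attains the exhaustive-enumeration optimum on 5 features", {
  ds <- synth_peptides(50, 50, mechanism = "composition", effect = 1.2,
                       seed = 53)
  feats <- c("F2", "F8", "F9", "F16", "F18")
  ctrl <- ga_control(pop_size = 20, max_generations = 15,
                     internal_folds = 3, ntree = 40)
  res <- ga_select(ds, feats, control = ctrl, seed = 7)
  # brute force over all 31 non-empty subsets on the identical fold cache
  oof <- res$oof
  best_bf <- -Inf
  for (mask in 1:(2^5 - 1)) {
    bits <- as.integer(intToBits(mask)[1:5])
    best_bf <- max(best_bf, fitness_from_scores(bits, oof))
  }
  expect_equal(res$best_fitness, best_bf)
})

test_that("the GA-fitted model predicts and exposes its subset", {
  ds <- synth_peptides(30, 30, mechanism = "composition", effect = 2,
                       seed = 59)
  fit <- ga_ensemble(ds, features = c("F2", "F9"), control = tiny_control(),
                     seed = 5)
  expect_s3_class(fit, "ga_ensemble")
  bits <- coef(fit)
  expect_length(bits, 2L)
  expect_true(all(bits %in% 0:1))
  scores <- predict(fit, ds)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_output(print(fit), "selected features")
  expect_output(summary(fit), "Chromosomes tried")
})
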