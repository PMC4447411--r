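# Genetic-algorithm search over the 2^18 feature-subset space.
#
# A chromosome is an 18-bit indicator of which encoders join the ensemble;
# its fitness is the internal stratified 5-fold cross-validation AUC of the
# subset's score-averaging ensemble on the training set (pooled out-of-fold
# scores). Because score averaging combines per-feature base predictors
# independently, each feature's out-of-fold score vector can be computed
# once per training set; any chromosome's fitness is then the AUC of the
# row means of the selected columns. The search itself uses elitist
# selection, uniform crossover and per-bit flip mutation.

#' GA configuration
#'
#' @param pop_size population size (default 100).
#' @param max_generations maximum number of population updates (default 100).
#' @param elite number of best chromosomes copied unchanged each generation.
#' @param crossover_fraction fraction of the non-elite offspring produced by
#'   uniform crossover (the rest are mutation-only children).
#' @param mutation_rate per-bit flip probability for mutation children
#'   (default 1/18).
#' @param stall_window stop when the best fitness has improved by less than
#'   `stall_tol` over this many consecutive generations.
#' @param stall_tol minimum improvement counted as progress (default 1e-6).
#' @param internal_folds folds of the internal cross-validation fitness
#'   (default 5).
#' @param ntree trees per base forest inside the fitness evaluation.
#' @return list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 100L, max_generations = 100L, elite = 2L,
                       crossover_fraction = 0.8, mutation_rate = 1 / 18,
                       stall_window = 50L, stall_tol = 1e-6,
                       internal_folds = 5L, ntree = 500L) {
  stopifnot(pop_size >= 2L, max_generations >= 1L, elite >= 0L,
            elite < pop_size, crossover_fraction >= 0, crossover_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1, internal_folds >= 2L)
  structure(list(pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 elite = as.integer(elite),
                 crossover_fraction = crossover_fraction,
                 mutation_rate = mutation_rate,
                 stall_window = as.integer(stall_window),
                 stall_tol = stall_tol,
                 internal_folds = as.integer(internal_folds),
                 ntree = as.integer(ntree)),
            class = "ga_control")
}

#' Stratified fold assignment
#'
#' Random fold labels balanced within each class, so every fold keeps the
#' overall class ratio (up to rounding).
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed integer seed (folds are drawn from a temporary RNG state).
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2L, length(labels) >= k)
  if (min(table(labels)) < k)
    stop("too few samples in a class for ", k, "-fold stratification")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      i <- which(labels == cls)
      folds[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  folds
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Per-feature internal out-of-fold score matrix
#'
#' For every candidate encoder, trains one base forest per internal fold on
#' the remaining folds and scores the held-out fold, giving each sample one
#' out-of-fold score per feature. The similarity profile (F5) refits its
#' reference on each internal training fold, so no held-out sequence ever
#' enters its own reference. The fitness of any feature subset is the AUC
#' of the row means over its columns ([fitness_from_scores()]).
#'
#' @param train labeled `peptide_dataset`.
#' @param features candidate encoder ids.
#' @param lambda lag overrides as in [encode_features()].
#' @param context an [encoder_context()].
#' @param folds internal fold count.
#' @param seed integer seed (fold draw + forest seeds derive from it).
#' @param ntree trees per base forest.
#' @return list with `scores` (n x length(features) matrix), `labels`,
#'   `fold` (internal fold ids).
#' @export
internal_cv_scores <- function(train, features, lambda = NULL,
                               context = encoder_context(), folds = 5L,
                               seed = 1L, ntree = 500L) {
  stopifnot(inherits(train, "peptide_dataset"))
  labels <- train$label
  if (anyNA(labels)) stop("training peptides must all be labeled")
  fold <- stratified_folds(labels, folds, seed = seed)
  plain <- setdiff(features, "F5")
  blocks <- if (length(plain))
    encode_features(train, plain, lambda, context) else list()
  scores <- matrix(NA_real_, nrow(train), length(features),
                   dimnames = list(NULL, features))
  for (f in seq_len(folds)) {
    te <- fold == f
    tr <- !te
    for (k in seq_along(features)) {
      id <- features[k]
      if (id == "F5") {
        ref <- fit_similarity_reference(train$sequence[tr])
        x_tr <- similarity_scores(train$sequence[tr], ref)
        x_te <- similarity_scores(train$sequence[te], ref)
      } else {
        x_tr <- blocks[[id]][tr, , drop = FALSE]
        x_te <- blocks[[id]][te, , drop = FALSE]
      }
      # seed keyed to the feature's identity (not its position in the
      # candidate list) so a subset's scores match a full-set cache exactly
      fnum <- match(id, feature_catalog()$id)
      base <- train_base(x_tr, labels[tr],
                         seed = seed + 101L * f + 7919L * fnum, ntree = ntree)
      scores[te, k] <- predict_base(base, x_te)
    }
  }
  list(scores = scores, labels = labels, fold = fold)
}

#' Fitness of a feature subset from precomputed out-of-fold scores
#'
#' @param bits 0/1 vector over the candidate features (at least one set).
#' @param oof result of [internal_cv_scores()].
#' @return internal-CV AUC of the subset's score-averaging ensemble.
#' @export
fitness_from_scores <- function(bits, oof) {
  sel <- which(bits == 1L)
  if (length(sel) == 0L) stop("empty feature subset")
  roc_auc(rowMeans(oof$scores[, sel, drop = FALSE]), oof$labels)
}

#' Fitness of one chromosome (internal-CV AUC)
#'
#' Convenience wrapper that computes the internal out-of-fold scores for the
#' selected features and returns the pooled-fold AUC. [ga_select()] computes
#' the per-feature scores once and reuses them for every chromosome.
#'
#' @inheritParams internal_cv_scores
#' @param bits 0/1 vector over `features`.
#' @return AUC in \[0, 1\].
#' @export
fitness_eval <- function(bits, train, features = feature_catalog()$id,
                         lambda = NULL, context = encoder_context(),
                         folds = 5L, seed = 1L, ntree = 500L) {
  stopifnot(length(bits) == length(features))
  sel <- features[bits == 1L]
  if (length(sel) == 0L) stop("empty feature subset")
  oof <- internal_cv_scores(train, sel, lambda, context, folds, seed, ntree)
  roc_auc(rowMeans(oof$scores), oof$labels)
}

# one population update: elitism + rank-based selection + uniform crossover
# + per-bit mutation; all-zero offspring get one random bit set (repair)
evolve_population <- function(pop, fitness, control) {
  n <- nrow(pop)
  nb <- ncol(pop)
  ord <- order(fitness, decreasing = TRUE)
  elite <- pop[ord[seq_len(control$elite)], , drop = FALSE]
  n_rest <- n - control$elite
  n_x <- round(control$crossover_fraction * n_rest)
  # rank-based parent selection: probability proportional to reversed rank
  pr <- rank(fitness)  # worst = 1
  pick <- function(m) sample.int(n, m, replace = TRUE, prob = pr)
  children <- matrix(0L, n_rest, nb)
  if (n_x > 0) {
    p1 <- pop[pick(n_x), , drop = FALSE]
    p2 <- pop[pick(n_x), , drop = FALSE]
    mask <- matrix(stats::runif(n_x * nb) < 0.5, n_x, nb)
    children[seq_len(n_x), ] <- ifelse(mask, p1, p2)
  }
  if (n_rest > n_x) {
    idx <- (n_x + 1L):n_rest
    parents <- pop[pick(length(idx)), , drop = FALSE]
    flip <- matrix(stats::runif(length(idx) * nb) < control$mutation_rate,
                   length(idx), nb)
    children[idx, ] <- ifelse(flip, 1L - parents, parents)
  }
  out <- rbind(elite, children)
  # repair all-zero chromosomes
  zero <- rowSums(out) == 0L
  if (any(zero))
    out[cbind(which(zero), sample.int(nb, sum(zero), replace = TRUE))] <- 1L
  storage.mode(out) <- "integer"
  out
}

#' GA search for the best feature subset
#'
#' Runs the genetic algorithm over subsets of the candidate encoders,
#' maximizing internal cross-validation AUC on the training set. Per-feature
#' out-of-fold scores are computed once and cached, so each distinct
#' chromosome costs only an averaging and a rank statistic. Terminates when
#' the best fitness has improved by less than `stall_tol` over
#' `stall_window` generations, or at `max_generations`.
#'
#' @inheritParams internal_cv_scores
#' @param control a [ga_control()].
#' @param seed integer seed governing fold draw, forest seeds and all GA
#'   randomness.
#' @return object of class `ga_result`: `best_bits` (named 0/1 vector),
#'   `best_fitness`, `history` (per-generation best/mean fitness),
#'   `evaluations` (distinct chromosomes evaluated), `features`, `oof`.
#' @export
ga_select <- function(train, features = feature_catalog()$id, lambda = NULL,
                      context = encoder_context(), control = ga_control(),
                      seed = 1L) {
  oof <- internal_cv_scores(train, features, lambda, context,
                            folds = control$internal_folds, seed = seed,
                            ntree = control$ntree)
  nb <- length(features)
  cache <- new.env(parent = emptyenv())
  eval_pop <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i) {
      key <- paste(pop[i, ], collapse = "")
      if (is.null(cache[[key]]))
        cache[[key]] <- fitness_from_scores(pop[i, ], oof)
      cache[[key]]
    }, numeric(1))
  }
  history <- data.frame(generation = integer(), best = numeric(),
                        mean = numeric())
  with_seed(seed + 483L, {
    pop <- matrix(as.integer(stats::runif(control$pop_size * nb) < 0.5),
                  control$pop_size, nb)
    zero <- rowSums(pop) == 0L
    if (any(zero))
      pop[cbind(which(zero), sample.int(nb, sum(zero), TRUE))] <- 1L
    fit <- eval_pop(pop)
    history <- rbind(history, data.frame(generation = 0L, best = max(fit),
                                         mean = mean(fit)))
    best_so_far <- max(fit)
    last_improve <- 0L
    for (g in seq_len(control$max_generations)) {
      pop <- evolve_population(pop, fit, control)
      fit <- eval_pop(pop)
      history <- rbind(history, data.frame(generation = g, best = max(fit),
                                           mean = mean(fit)))
      if (max(fit) > best_so_far + control$stall_tol) {
        best_so_far <- max(fit)
        last_improve <- g
      }
      if (g - last_improve >= control$stall_window) break
    }
  })
  keys <- ls(cache)
  fits <- vapply(keys, function(k) cache[[k]], numeric(1))
  best_key <- keys[which.max(fits)]
  best_bits <- as.integer(strsplit(best_key, "")[[1]])
  names(best_bits) <- features
  structure(list(best_bits = best_bits, best_fitness = max(fits),
                 history = history, evaluations = length(keys),
                 features = features, oof = oof, control = control,
                 seed = seed),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA feature selection: best internal-CV AUC %.4f with subset {%s}\n",
              x$best_fitness,
              paste(names(x$best_bits)[x$best_bits == 1L], collapse = ", ")))
  cat(sprintf("  %d generations, %d distinct chromosomes evaluated\n",
              max(x$history$generation), x$evaluations))
  invisible(x)
}
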