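# Evaluation protocol: repeated stratified 10-fold cross-validation with
# per-fold and per-run metrics, merged-vector baselines, between-feature
# AUC correlation, subset-frequency accounting for GA-in-the-loop runs,
# and significance tests against paired runs or published mean scores.

#' Repeated stratified cross-validation
#'
#' Runs `runs` independent rounds of stratified `folds`-fold
#' cross-validation. Three pipelines are supported: `"ensemble"` trains the
#' fixed-subset score-averaging ensemble on each training fold (a single
#' feature id gives the individual feature-based model); `"merged"`
#' concatenates the feature blocks and trains one forest on the merged
#' vector; `"ga"` re-runs the genetic algorithm on every training fold so
#' the subset is re-selected per fold.
#'
#' Per fold, threshold metrics (threshold 0.5) and the fold AUC are
#' recorded; per run, metrics come from the pooled confusion counts and the
#' run AUC from the pooled out-of-fold scores (every peptide is tested
#' exactly once per run).
#'
#' @param data labeled `peptide_dataset`.
#' @param mode `"ensemble"`, `"merged"` or `"ga"`.
#' @param features encoder ids: the fixed subset (`"ensemble"`), the merged
#'   list (`"merged"`), or the GA candidate set (`"ga"`).
#' @param lambda lag overrides as in [encode_features()].
#' @param runs number of independent repetitions (study protocol: 20).
#' @param folds folds per run (study protocol: 10).
#' @param seed integer seed; run r uses fold seed `seed + r`.
#' @param ntree trees per forest.
#' @param control [ga_control()] used in `"ga"` mode.
#' @param context an [encoder_context()].
#' @return object of class `cv_report`: `folds` (per-fold rows with SN, SP,
#'   ACC, MCC, AUC and the selected subset bits), `runs` (per-run pooled
#'   metrics), plus the protocol settings.
#' @examples
#' ds <- synth_peptides(30, 30, mechanism = "composition", effect = 2, seed = 1)
#' rep <- repeated_cv(ds, features = "F2", runs = 2, folds = 3,
#'                    seed = 1, ntree = 60)
#' summary(rep)
#' @export
repeated_cv <- function(data, mode = c("ensemble", "merged", "ga"),
                        features = feature_catalog()$id, lambda = NULL,
                        runs = 20L, folds = 10L, seed = 1L, ntree = 500L,
                        control = ga_control(), context = encoder_context()) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "peptide_dataset"), nrow(data) >= folds)
  if (anyNA(data$label)) stop("all peptides must be labeled for evaluation")
  labels <- data$label
  fold_rows <- list()
  run_rows <- list()
  for (r in seq_len(runs)) {
    fold_id <- stratified_folds(labels, folds, seed = seed + r)
    pooled_scores <- numeric(nrow(data))
    for (f in seq_len(folds)) {
      te <- fold_id == f
      train <- data[!te, , drop = FALSE]
      attr(train, "name") <- attr(data, "name")
      class(train) <- c("peptide_dataset", "data.frame")
      fit_seed <- seed + 1009L * r + 13L * f
      if (mode == "ga") {
        sel <- ga_select(train, features, lambda, context, control,
                         seed = fit_seed)
        chosen <- names(sel$best_bits)[sel$best_bits == 1L]
        model <- ensemble_fit(train, chosen, lambda, context,
                              seed = fit_seed, ntree = ntree)
        bits <- paste(sel$best_bits, collapse = "")
        scores <- predict(model, data$sequence[te])
      } else if (mode == "merged") {
        ctx <- context
        ctx$ref <- fit_similarity_reference(train)
        x_tr <- do.call(cbind, encode_features(train, features, lambda, ctx))
        x_te <- do.call(cbind,
                        encode_features(data$sequence[te], features, lambda,
                                        ctx))
        base <- train_base(x_tr, train$label, seed = fit_seed, ntree = ntree)
        scores <- predict_base(base, x_te)
        bits <- paste(rep(1L, length(features)), collapse = "")
      } else {
        model <- ensemble_fit(train, features, lambda, context,
                              seed = fit_seed, ntree = ntree)
        scores <- predict(model, data$sequence[te])
        bits <- paste(rep(1L, length(features)), collapse = "")
      }
      pooled_scores[te] <- scores
      cm <- compute_metrics(confusion_counts(classify_scores(scores),
                                             labels[te]))
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(run = r, fold = f, SN = cm[["SN"]], SP = cm[["SP"]],
                   ACC = cm[["ACC"]], MCC = cm[["MCC"]],
                   AUC = roc_auc(scores, labels[te]), subset = bits)
    }
    cm <- compute_metrics(confusion_counts(classify_scores(pooled_scores),
                                           labels))
    run_rows[[r]] <- data.frame(run = r, SN = cm[["SN"]], SP = cm[["SP"]],
                                ACC = cm[["ACC"]], MCC = cm[["MCC"]],
                                AUC = roc_auc(pooled_scores, labels))
  }
  structure(list(folds = do.call(rbind, fold_rows),
                 runs = do.call(rbind, run_rows),
                 mode = mode, features = features, n_runs = runs,
                 n_folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV report: %s pipeline, %d run(s) x %d-fold, features {%s}\n",
              x$mode, x$n_runs, x$n_folds,
              paste(x$features, collapse = ", ")))
  print(summary(x))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  m <- colMeans(object$runs[, c("SN", "SP", "ACC", "MCC", "AUC")],
                na.rm = TRUE)
  round(m, 4)
}

#' Write a CV report to TSV
#'
#' One row per fold (`run, fold, SN, SP, ACC, MCC, AUC, subset`).
#'
#' @param report a `cv_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  utils::write.table(report$folds, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Between-feature correlation of fold-level AUC scores
#'
#' Absolute Pearson correlation between the fold AUC vectors of individual
#' feature-based models evaluated on identical splits; high values flag
#' redundant features. Zero-variance columns give `NA` entries with a
#' warning.
#'
#' @param fold_auc numeric matrix, rows = folds (aligned across features),
#'   columns = features.
#' @return symmetric matrix of |Pearson r| with unit diagonal.
#' @export
correlation_table <- function(fold_auc) {
  stopifnot(is.matrix(fold_auc), nrow(fold_auc) >= 3L)
  sds <- apply(fold_auc, 2, stats::sd)
  if (any(sds == 0)) warning("zero-variance AUC column(s): entries set NA")
  out <- abs(suppressWarnings(stats::cor(fold_auc)))
  out[, sds == 0] <- NA_real_
  out[sds == 0, ] <- NA_real_
  diag(out) <- 1
  out
}

#' Significance test between AUC score samples
#'
#' Paired two-sided t-test between two equal-length per-run AUC samples, or
#' a one-sample t-test of a run sample against a published mean score.
#' Zero-variance differences (identical samples) return `NA` with a warning
#' rather than a spurious p-value.
#'
#' @param x numeric vector of per-run AUC scores.
#' @param y optional paired sample of the same length.
#' @param mu optional scalar reference mean (used when `y` is missing).
#' @return the `htest` object from [stats::t.test()], or `NA` (with a
#'   warning) when the differences have zero variance.
#' @export
compare_auc <- function(x, y = NULL, mu = NULL) {
  if (is.null(y) == is.null(mu))
    stop("supply exactly one of 'y' (paired) or 'mu' (published mean)")
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    if (stats::sd(x - y) == 0) {
      warning("zero-variance paired differences; p-value undefined")
      return(NA)
    }
    return(stats::t.test(x, y, paired = TRUE))
  }
  if (stats::sd(x) == 0) {
    warning("zero-variance sample; p-value undefined")
    return(NA)
  }
  stats::t.test(x, mu = mu)
}

#' Published mean AUC scores of prior predictors
#'
#' Mean 10-fold cross-validation AUC scores reported for earlier
#' immunogenicity predictors on the two benchmark datasets (POPI, POPISK,
#' PAAQD and the average-scoring ensemble that preceded this method), kept
#' for one-sample significance tests when only published means are
#' available. These numbers are quoted results of other tools, not outputs
#' of this package.
#'
#' @return data frame with columns `dataset`, `method`, `AUC`.
#' @export
reference_auc <- function() {
  data.frame(
    dataset = c("IMMA2", "IMMA2", "IMMA2", "IMMA2",
                "PAAQD", "PAAQD"),
    method = c("POPI", "POPISK", "PAAQD", "average-scoring ensemble",
               "PAAQD", "average-scoring ensemble"),
    AUC = c(0.64, 0.74, 0.747, 0.766, 0.749, 0.773),
    stringsAsFactors = FALSE
  )
}

#' Feature frequencies in GA-selected subsets
#'
#' Counts, for each candidate feature, in how many of the report's
#' per-fold optimal subsets it appears (a GA-in-the-loop report with 20
#' runs x 10 folds yields counts in 0..200).
#'
#' @param report a `cv_report` from `repeated_cv(..., mode = "ga")`.
#' @return named integer vector over the candidate features.
#' @export
subset_frequencies <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  bits <- do.call(rbind, lapply(strsplit(report$folds$subset, ""),
                                as.integer))
  counts <- colSums(bits)
  names(counts) <- report$features
  counts
}
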