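# Per-feature random-forest base classifiers and the score-averaging
# ensemble. Each selected encoder gets its own forest trained on that
# encoder's block; the ensemble predicts with the unweighted mean of the
# base predictors' positive-class probabilities.

#' Train a base predictor on one feature block
#'
#' Fits a random forest (default 500 trees, sqrt(p) candidate variables per
#' split, unlimited depth) on a single encoder's feature matrix. The forest
#' seed is set explicitly so training is reproducible.
#'
#' @param x numeric feature matrix (rows = peptides).
#' @param y 0/1 label vector aligned with `x`; both classes required.
#' @param seed integer RNG seed for the forest.
#' @param ntree number of trees.
#' @param mtry variables tried per split (default `floor(sqrt(ncol(x)))`).
#' @return object of class `base_predictor`.
#' @export
train_base <- function(x, y, seed = 1L, ntree = 500L, mtry = NULL) {
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2L) stop("both classes required to train")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  yf <- factor(y, levels = c(0L, 1L))
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = yf, ntree = ntree,
                                       mtry = mtry)
  structure(list(forest = forest, ntree = ntree, mtry = mtry, seed = seed),
            class = "base_predictor")
}

#' Positive-class scores from a base predictor
#'
#' @param object a [train_base()] fit.
#' @param x feature matrix with the same columns the predictor was trained on.
#' @return numeric vector of positive-class probabilities in \[0, 1\].
#' @export
predict_base <- function(object, x) {
  stopifnot(inherits(object, "base_predictor"))
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  unname(stats::predict(object$forest, x, type = "prob")[, "1"])
}

#' Fit a fixed-subset score-averaging ensemble
#'
#' Encodes the training peptides with the chosen encoders, trains one
#' random-forest base predictor per encoder, and combines them by averaging
#' positive-class scores. All fitted context (the F5 similarity reference,
#' the structure annotator, lookup tables) is stored inside the model so
#' prediction needs only new sequences.
#'
#' @param train a labeled `peptide_dataset`.
#' @param features encoder ids to use, e.g. `c("F2", "F5", "F17")`.
#' @param lambda lag/order overrides as in [encode_features()].
#' @param context an [encoder_context()]; its similarity reference is
#'   refitted on `train` so F5 always scores against the training fold.
#' @param seed integer seed; per-feature forest seeds are derived from it.
#' @param ntree trees per forest.
#' @return object of class `epi_ensemble`.
#' @examples
#' ds <- synth_peptides(30, 30, mechanism = "composition", effect = 2, seed = 1)
#' fit <- ensemble_fit(ds, c("F2", "F8"), seed = 1, ntree = 60)
#' predict(fit, ds)[1:3]
#' @export
ensemble_fit <- function(train, features, lambda = NULL,
                         context = encoder_context(), seed = 1L,
                         ntree = 500L) {
  stopifnot(inherits(train, "peptide_dataset"))
  if (length(features) == 0L) stop("at least one feature required")
  if (anyNA(train$label)) stop("training peptides must all be labeled")
  context$ref <- fit_similarity_reference(train)
  blocks <- encode_features(train, features, lambda, context)
  bases <- vector("list", length(features))
  names(bases) <- features
  for (k in seq_along(features)) {
    bases[[k]] <- train_base(blocks[[k]], train$label,
                             seed = seed + 1000L * k, ntree = ntree)
  }
  structure(list(features = features,
                 lambda = resolve_lambda(features, lambda),
                 bases = bases, context = context, seed = seed,
                 n_train = nrow(train)),
            class = "epi_ensemble")
}

#' @export
print.epi_ensemble <- function(x, ...) {
  cat(sprintf("Score-averaging ensemble: %d base predictor(s) [%s], %d training peptides\n",
              length(x$features), paste(x$features, collapse = ", "),
              x$n_train))
  invisible(x)
}

#' Predict immunogenicity scores or classes
#'
#' @param object an [ensemble_fit()] model.
#' @param newdata a `peptide_dataset` or character vector of 9-mers.
#' @param type `"score"` for the averaged positive-class probability,
#'   `"class"` for thresholded 0/1 labels.
#' @param threshold classification threshold in \[0, 1\]; a score equal to
#'   the threshold classifies positive.
#' @param ... unused.
#' @return numeric vector of scores in \[0, 1\], or integer 0/1 classes.
#' @export
predict.epi_ensemble <- function(object, newdata, type = c("score", "class"),
                                 threshold = 0.5, ...) {
  type <- match.arg(type)
  blocks <- encode_features(newdata, object$features, object$lambda,
                            object$context)
  scores <- rowMeans(vapply(object$features,
                            function(f) predict_base(object$bases[[f]],
                                                     blocks[[f]]),
                            numeric(nrow(blocks[[1]]))))
  if (type == "score") return(scores)
  classify_scores(scores, threshold)
}

#' Threshold scores into classes
#'
#' Scores greater than or equal to the threshold are classified positive
#' (ties go positive).
#'
#' @param scores numeric scores in \[0, 1\].
#' @param threshold real in \[0, 1\].
#' @return integer 0/1 vector.
#' @export
classify_scores <- function(scores, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  as.integer(scores >= threshold)
}

MODEL_FORMAT <- "epiGA-model-1"

#' Save / load a trained model
#'
#' Single-file serialized container with an embedded format-version string;
#' a reloaded model reproduces predictions exactly.
#'
#' @param model a trained `epi_ensemble` or `ga_ensemble`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("epi_ensemble", "ga_ensemble")))
  saveRDS(list(format = MODEL_FORMAT, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable model file ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop("not an epiGA model file (or version mismatch): ", path)
  obj$model
}
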