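#' Fit a GA-selected score-averaging ensemble
#'
#' The package's main fitting function. Runs the genetic algorithm on the
#' training peptides to find the feature subset with the best internal
#' cross-validation AUC, then trains the final score-averaging ensemble on
#' the full training set using that subset.
#'
#' @param data a labeled `peptide_dataset` (9-mers with 0/1 labels).
#' @param features candidate encoder ids (default all 18; see
#'   [feature_catalog()]).
#' @param lambda lag/order overrides as in [encode_features()].
#' @param control a [ga_control()] holding population size, operator rates,
#'   termination and internal-CV settings.
#' @param context an [encoder_context()] (structure annotator, lookup
#'   tables); the F5 similarity reference is fitted internally.
#' @param seed integer seed; the GA search, internal folds and all forest
#'   seeds derive from it, so identical inputs reproduce the fit exactly.
#' @param ntree trees per base forest in the final model (default the
#'   control's `ntree`).
#' @return an object of class `ga_ensemble` with components `selection`
#'   (the [ga_select()] result) and `model` (the fitted [ensemble_fit()]).
#' @examples
#' ds <- synth_peptides(40, 40, mechanism = "composition", effect = 2, seed = 1)
#' fit <- ga_ensemble(ds, features = c("F2", "F8", "F9"),
#'                    control = ga_control(pop_size = 10, max_generations = 3,
#'                                         ntree = 50), seed = 1)
#' fit
#' predict(fit, ds)[1:3]
#' @export
ga_ensemble <- function(data, features = feature_catalog()$id, lambda = NULL,
                        control = ga_control(), context = encoder_context(),
                        seed = 1L, ntree = control$ntree) {
  selection <- ga_select(data, features, lambda, context, control, seed)
  chosen <- names(selection$best_bits)[selection$best_bits == 1L]
  model <- ensemble_fit(data, chosen, lambda, context,
                        seed = seed + 271L, ntree = ntree)
  structure(list(selection = selection, model = model, call = match.call()),
            class = "ga_ensemble")
}

#' @export
print.ga_ensemble <- function(x, ...) {
  cat("GA-selected score-averaging ensemble\n")
  cat(sprintf("  selected features: %s\n",
              paste(x$model$features, collapse = ", ")))
  cat(sprintf("  internal-CV AUC (fitness): %.4f\n",
              x$selection$best_fitness))
  invisible(x)
}

#' @export
summary.ga_ensemble <- function(object, ...) {
  sel <- object$selection
  cat("GA-selected score-averaging ensemble\n\n")
  cat(sprintf("Candidate features : %d (%s)\n", length(sel$features),
              paste(sel$features, collapse = ", ")))
  cat(sprintf("Selected subset    : %s\n",
              paste(object$model$features, collapse = ", ")))
  cat(sprintf("Internal-CV AUC    : %.4f\n", sel$best_fitness))
  cat(sprintf("Generations run    : %d\n", max(sel$history$generation)))
  cat(sprintf("Chromosomes tried  : %d of %s possible\n", sel$evaluations,
              format(2^length(sel$features), big.mark = ",")))
  cat("\nFitness history (last 5 generations):\n")
  print(utils::tail(sel$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
predict.ga_ensemble <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
coef.ga_ensemble <- function(object, ...) {
  object$selection$best_bits
}

#' Plot the GA fitness trajectory
#'
#' Best and mean internal-CV AUC per generation.
#'
#' @param x a [ga_ensemble()] or `ga_result` object.
#' @param ... passed to [plot()].
#' @export
plot.ga_ensemble <- function(x, ...) {
  plot(x$selection, ...)
}

#' @export
plot.ga_result <- function(x, ...) {
  h <- x$history
  plot(h$generation, h$best, type = "s", lwd = 2,
       xlab = "generation", ylab = "internal-CV AUC",
       ylim = range(c(h$best, h$mean)), ...)
  graphics::lines(h$generation, h$mean, lty = 2)
  graphics::legend("bottomright", c("best", "population mean"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(x)
}
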