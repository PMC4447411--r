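# Smith-Waterman pairwise similarity profile (F5).
#
# A peptide is represented by its local-alignment scores against every
# sequence of the training set, so this encoder must be fitted: the
# reference is always the current training fold, never the full dataset,
# and the fitted reference travels inside the trained model.

#' Fit the similarity reference for the pairwise similarity profile (F5)
#'
#' Freezes the training sequences (in order) together with the alignment
#' parameters. Scoring uses Smith-Waterman local alignment under BLOSUM62
#' with affine gaps (a gap of length k costs `gap_open + k * gap_ext`).
#'
#' @param train a `peptide_dataset` (or character vector) of training
#'   sequences; the encoder's output dimension equals its size.
#' @param gap_open,gap_ext affine gap penalties (defaults 10 and 1).
#' @return an object of class `similarity_reference`.
#' @export
fit_similarity_reference <- function(train, gap_open = 10, gap_ext = 1) {
  seqs <- if (inherits(train, "peptide_dataset")) train$sequence
          else toupper(train)
  if (length(seqs) == 0L) stop("empty similarity reference")
  structure(list(sequences = seqs, gap_open = gap_open, gap_ext = gap_ext),
            class = "similarity_reference")
}

#' @export
print.similarity_reference <- function(x, ...) {
  cat(sprintf("Similarity reference: %d sequences (BLOSUM62, gap %g/%g)\n",
              length(x$sequences), x$gap_open, x$gap_ext))
  invisible(x)
}

blosum62 <- function() {
  if (is.null(.tables_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .tables_env$blosum62 <- e$BLOSUM62
  }
  .tables_env$blosum62
}

#' Smith-Waterman similarity scores against a fitted reference
#'
#' @param sequences character vector of query 9-mers.
#' @param ref a [fit_similarity_reference()] object.
#' @return numeric matrix, `length(sequences)` rows x reference-size columns,
#'   column j holding local-alignment scores against reference sequence j.
#' @export
similarity_scores <- function(sequences, ref) {
  stopifnot(inherits(ref, "similarity_reference"))
  subject_set <- Biostrings::AAStringSet(ref$sequences)
  m <- t(vapply(sequences, function(q) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      subject_set, Biostrings::AAString(q), type = "local",
      substitutionMatrix = blosum62(),
      gapOpening = ref$gap_open, gapExtension = ref$gap_ext))
  }, numeric(length(ref$sequences))))
  rownames(m) <- NULL
  m
}

#' Encode one peptide as its similarity profile (F5)
#'
#' @param sequence a 9-mer peptide.
#' @param ref a fitted [fit_similarity_reference()].
#' @return numeric vector of length `length(ref$sequences)`.
#' @export
encode_similarity <- function(sequence, ref) {
  as.numeric(similarity_scores(toupper(sequence), ref))
}
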