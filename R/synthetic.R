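# Synthetic peptide datasets with controllable planted signal.
#
# Three mechanisms, each detectable by a matched encoder family and (by
# construction) near-invisible to mismatched ones, so pipeline stages and
# the GA's subset recovery can be validated end to end without benchmark
# downloads. Effect size 0 makes the two classes exchangeable draws from
# the same background (the null).

#' Generate a labeled synthetic 9-mer dataset
#'
#' Negatives are drawn from the background residue distribution (uniform
#' over the 20 letters by default). Positives are perturbed according to
#' the mechanism:
#' \describe{
#'   \item{`composition`}{residues drawn from a tilted multinomial with
#'     weight `exp(effect)` on a designated residue subset
#'     (`LVIFM`, hydrophobic), detectable by composition-family encoders;}
#'   \item{`motif`}{a fixed residue (`L`) planted at a fixed position
#'     (position 2, an anchor-like choice) with probability `effect`
#'     (clamped to \[0, 1\]), invisible to composition at small effect but
#'     detectable by positional encoders such as the sparse profile;}
#'   \item{`property`}{residues drawn with weight `exp(effect * z)` where
#'     `z` is the standardized hydrophobicity scale, detectable by
#'     property-profile encoders.}
#' }
#' Duplicate sequences are resampled so datasets satisfy the no-duplicates
#' invariant; generation is deterministic per seed and leaves the global
#' RNG state untouched.
#'
#' @param n_pos,n_neg class sizes (each >= 1).
#' @param mechanism `"composition"`, `"motif"` or `"property"`.
#' @param effect effect size >= 0; 0 gives exchangeable classes.
#' @param seed integer seed.
#' @param background either `"uniform"` or a named 20-vector of residue
#'   probabilities.
#' @return a labeled `peptide_dataset` (positives first).
#' @examples
#' synth_peptides(3, 3, mechanism = "motif", effect = 0.9, seed = 7)
#' @export
synth_peptides <- function(n_pos, n_neg,
                           mechanism = c("composition", "motif", "property"),
                           effect = 0, seed = 1L, background = "uniform") {
  mechanism <- match.arg(mechanism)
  stopifnot(n_pos >= 1L, n_neg >= 1L, effect >= 0)
  if (identical(background, "uniform")) {
    bg <- rep(1 / 20, 20)
    names(bg) <- AA_ALPHABET
  } else {
    stopifnot(length(background) == 20L,
              setequal(names(background), AA_ALPHABET))
    bg <- background[AA_ALPHABET] / sum(background)
  }
  pos_w <- switch(mechanism,
    composition = {
      w <- bg
      tilt <- AA_ALPHABET %in% c("L", "V", "I", "F", "M")
      w[tilt] <- w[tilt] * exp(effect)
      w / sum(w)
    },
    motif = bg,
    property = {
      z <- standardize_scale(aa_property_table(HYDROPHOBICITY_ID))
      w <- bg * exp(effect * z)
      w / sum(w)
    })
  draw <- function(n, w, motif_prob = 0) {
    m <- matrix(sample(AA_ALPHABET, n * PEPTIDE_LENGTH, replace = TRUE,
                       prob = w), n, PEPTIDE_LENGTH)
    if (motif_prob > 0) {
      hit <- stats::runif(n) < motif_prob
      m[hit, 2L] <- "L"
    }
    apply(m, 1, paste, collapse = "")
  }
  with_seed(seed, {
    motif_prob <- if (mechanism == "motif") min(effect, 1) else 0
    seqs <- c(draw(n_pos, pos_w, motif_prob), draw(n_neg, bg))
    guard <- 0L
    while (anyDuplicated(seqs) && guard < 1000L) {
      dup <- which(duplicated(seqs))
      is_pos <- dup <= n_pos
      if (any(is_pos))
        seqs[dup[is_pos]] <- draw(sum(is_pos), pos_w, motif_prob)
      if (any(!is_pos))
        seqs[dup[!is_pos]] <- draw(sum(!is_pos), bg)
      guard <- guard + 1L
    }
    if (anyDuplicated(seqs)) stop("could not generate unique sequences")
    peptide_dataset(seqs, c(rep(1L, n_pos), rep(0L, n_neg)),
                    name = sprintf("synthetic-%s-%g", mechanism, effect))
  })
}
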