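# Structure annotations for the RASA (F17) and secondary-structure (F18)
# encoders. Predicted annotations normally come from an external structure
# predictor such as SABLE; the package consumes them through a small
# annotator interface so either a parsed report or the bundled per-letter
# surrogate can drive the encoders.

new_annotator <- function(fn, kind) {
  structure(list(annotate = fn, kind = kind), class = "structure_annotator")
}

#' @export
print.structure_annotator <- function(x, ...) {
  cat("Structure annotator:", x$kind, "\n")
  invisible(x)
}

#' Annotate a peptide with predicted structure
#'
#' @param annotator a `structure_annotator` ([surrogate_annotator()] or
#'   [sable_annotator()]).
#' @param sequence a 9-mer peptide sequence.
#' @return list with `rasa` (9 reals in \[0, 100\], percent exposed surface)
#'   and `ss` (9 labels from `H`/`E`/`C`).
#' @export
annotate_structure <- function(annotator, sequence) {
  stopifnot(inherits(annotator, "structure_annotator"))
  ann <- annotator$annotate(toupper(sequence))
  if (length(ann$rasa) != PEPTIDE_LENGTH || length(ann$ss) != PEPTIDE_LENGTH)
    stop("annotation length mismatch for ", sequence)
  if (any(ann$rasa < 0 | ann$rasa > 100))
    stop("RASA outside [0, 100] for ", sequence)
  if (!all(ann$ss %in% c("H", "E", "C")))
    stop("secondary-structure labels must be H/E/C")
  ann
}

#' Per-letter surrogate structure annotator
#'
#' A deterministic stand-in for a structure predictor, used so the full
#' pipeline runs closed-box: each residue receives a fixed relative
#' accessible surface area (its tripeptide accessible-surface scale value,
#' CHOC760101, rescaled to 0-100) and a fixed secondary-structure class
#' (its conformational-preference group: helix formers H, strand formers E,
#' coil formers C). This is NOT a structure prediction; supply parsed
#' predictor output via [sable_annotator()] for real annotations.
#'
#' @return a `structure_annotator`.
#' @export
surrogate_annotator <- function() {
  asa <- aa_property_table("CHOC760101")
  rasa_letter <- 100 * (asa - min(asa)) / (max(asa) - min(asa))
  grp <- ctd_attributes()$secondary_struct
  ss_letter <- c("H", "E", "C")[grp]
  names(ss_letter) <- names(grp)
  new_annotator(function(sequence) {
    ch <- pep_chars(sequence)
    list(rasa = unname(rasa_letter[ch]), ss = unname(ss_letter[ch]))
  }, "per-letter surrogate (not a structure prediction)")
}

#' Structure annotator backed by a parsed predictor report
#'
#' Parses a plain-text report of per-peptide structure predictions (e.g.
#' reformatted SABLE output) and serves annotations by sequence. The report
#' format is four lines per record:
#' \preformatted{
#' >identifier
#' ACDEFGHIK          # the 9-mer sequence
#' HHHCCCEEE          # 9 secondary-structure letters (H/E/C)
#' 12 40 3 88 ...     # 9 whitespace-separated RASA values in [0, 100]
#' }
#'
#' @param path report file.
#' @return a `structure_annotator` that errors on peptides absent from the
#'   report.
#' @export
sable_annotator <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no records in structure report ", path)
  if (any(diff(c(starts, length(lines) + 1L)) != 4L))
    stop("malformed structure report (expected 4 lines per record): ", path)
  recs <- lapply(starts, function(s) {
    sequence <- toupper(trimws(lines[s + 1L]))
    ss <- pep_chars(toupper(trimws(lines[s + 2L])))
    rasa <- as.numeric(strsplit(trimws(lines[s + 3L]), "\\s+")[[1]])
    list(sequence = sequence, ss = ss, rasa = rasa)
  })
  names(recs) <- vapply(recs, `[[`, character(1), "sequence")
  new_annotator(function(sequence) {
    r <- recs[[sequence]]
    if (is.null(r)) stop("no structure annotation for ", sequence)
    list(rasa = r$rasa, ss = r$ss)
  }, sprintf("parsed report (%d records)", length(recs)))
}
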