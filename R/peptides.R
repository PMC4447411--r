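#' The 20 standard amino-acid letters
#'
#' One-letter codes of the 20 standard amino acids, alphabetically ordered.
#' All encoders index their composition dimensions in this order.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Peptide length handled by the package
#'
#' MHC class I (HLA-A2) epitopes modelled here are 9-mers.
#' @export
PEPTIDE_LENGTH <- 9L

# splits a peptide into its residue letters
pep_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Validate 9-mer peptide sequences
#'
#' Checks that each sequence is exactly 9 residues long and uses only the 20
#' standard amino-acid letters (uppercase canonical form; lowercase input is
#' accepted and upcased).
#'
#' @param sequences character vector of candidate peptide sequences.
#' @return character vector of reasons, `NA` where a sequence is valid.
#' @export
validate_peptides <- function(sequences) {
  sequences <- toupper(sequences)
  reason <- rep(NA_character_, length(sequences))
  bad_len <- nchar(sequences) != PEPTIDE_LENGTH
  reason[bad_len] <- sprintf("length %d != %d", nchar(sequences)[bad_len],
                             PEPTIDE_LENGTH)
  ok <- !bad_len
  if (any(ok)) {
    pat <- sprintf("^[%s]{%d}$", paste(AA_ALPHABET, collapse = ""),
                   PEPTIDE_LENGTH)
    bad_chr <- ok & !grepl(pat, sequences)
    reason[bad_chr] <- "non-standard residue"
  }
  reason
}

#' Construct a labeled peptide dataset
#'
#' The central data container: an ordered set of validated 9-mer peptides
#' with an optional binary immunogenicity label (1 = immunogenic epitope,
#' 0 = non-immunogenic, `NA` = unlabeled).
#'
#' @param sequences character vector of 9-mer sequences over the 20-letter
#'   alphabet.
#' @param labels integer/numeric vector of 0/1 labels (or `NA`), recycled if
#'   scalar; `NULL` for a fully unlabeled set.
#' @param name dataset name used in printing.
#' @param skip_invalid drop records failing validation (with a warning)
#'   instead of raising an error.
#' @param dedup drop duplicated sequences (keeping the first occurrence)
#'   instead of raising an error.
#' @return an object of class `peptide_dataset` (a data frame with columns
#'   `sequence` and `label`).
#' @examples
#' ds <- peptide_dataset(c("ACDEFGHIK", "LLLLLLLLL"), c(1, 0))
#' ds
#' @export
peptide_dataset <- function(sequences, labels = NULL, name = "peptides",
                            skip_invalid = FALSE, dedup = FALSE) {
  sequences <- toupper(as.character(sequences))
  if (is.null(labels)) labels <- rep(NA_integer_, length(sequences))
  if (length(labels) == 1L) labels <- rep(labels, length(sequences))
  stopifnot(length(labels) == length(sequences))
  labels <- as.integer(labels)
  if (any(!is.na(labels) & !(labels %in% c(0L, 1L))))
    stop("labels must be 0, 1 or NA")

  reason <- validate_peptides(sequences)
  if (any(!is.na(reason))) {
    bad <- which(!is.na(reason))
    msg <- paste(sprintf("record %d ('%s'): %s", bad, sequences[bad],
                         reason[bad]), collapse = "; ")
    if (!skip_invalid) stop("invalid peptide(s): ", msg)
    warning("skipping ", length(bad), " invalid record(s): ", msg)
    sequences <- sequences[-bad]
    labels <- labels[-bad]
  }
  if (anyDuplicated(sequences)) {
    if (!dedup) stop("duplicate sequences present (use dedup = TRUE to drop)")
    keep <- !duplicated(sequences)
    warning("dropping ", sum(!keep), " duplicate sequence(s)")
    sequences <- sequences[keep]
    labels <- labels[keep]
  }
  if (length(sequences) == 0L) stop("no valid peptide records")
  out <- data.frame(sequence = sequences, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("peptide_dataset", "data.frame")
  out
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat(sprintf("Peptide dataset '%s': %d peptides (%d positive, %d negative, %d unlabeled)\n",
              attr(x, "name"), nrow(x), sum(x$label == 1L, na.rm = TRUE),
              sum(x$label == 0L, na.rm = TRUE), sum(is.na(x$label))))
  n_show <- min(6L, nrow(x))
  print.data.frame(utils::head(as.data.frame(x), n_show), row.names = FALSE)
  if (nrow(x) > n_show) cat("...\n")
  invisible(x)
}

#' Count positive / negative peptides
#'
#' @param x a `peptide_dataset`.
#' @return named integer vector with elements `positive`, `negative`,
#'   `unlabeled`.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "peptide_dataset"))
  c(positive = sum(x$label == 1L, na.rm = TRUE),
    negative = sum(x$label == 0L, na.rm = TRUE),
    unlabeled = sum(is.na(x$label)))
}

# ---- file formats -----------------------------------------------------------
#
# Two dialects:
#   tabular  - CSV/TSV with header "sequence,label", label in {0,1} (may be
#              absent for unlabeled sets)
#   fasta    - the label is the last '|'-separated token of the header line
#              (">id|...|1"); headers without a trailing 0/1 token give NA

detect_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "faa")) return("fasta")
  if (ext %in% c("csv", "tsv", "txt")) return("tabular")
  # sniff: FASTA records start with '>'
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) "fasta" else "tabular"
}

#' Read a peptide dataset from disk
#'
#' Supports two plain-text dialects. `tabular`: delimited text (comma or tab,
#' auto-detected) with a header containing `sequence` and optionally `label`
#' columns, label coded 0/1. `fasta`: standard FASTA where the immunogenicity
#' label is the last `|`-separated token of each header. The dialect is
#' auto-detected from the file extension/content unless given.
#'
#' @param path file to read.
#' @param dialect `"auto"`, `"tabular"` or `"fasta"`.
#' @param name dataset name; defaults to the file name.
#' @inheritParams peptide_dataset
#' @return a [peptide_dataset()].
#' @export
read_peptides <- function(path, dialect = c("auto", "tabular", "fasta"),
                          name = NULL, skip_invalid = FALSE, dedup = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") dialect <- detect_dialect(path)
  if (is.null(name)) name <- basename(path)

  if (dialect == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) stop("no records in ", path)
    headers <- names(seqs)
    tok <- vapply(strsplit(headers, "|", fixed = TRUE),
                  function(t) t[[length(t)]], character(1))
    labels <- ifelse(tok %in% c("0", "1"), as.integer(tok), NA_integer_)
    sequences <- as.character(seqs)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character", strip.white = TRUE)
    names(tab) <- tolower(names(tab))
    if (!"sequence" %in% names(tab))
      stop("tabular file must have a 'sequence' column: ", path)
    sequences <- tab$sequence
    labels <- if ("label" %in% names(tab)) as.integer(tab$label) else NULL
  }
  peptide_dataset(sequences, labels, name = name,
                  skip_invalid = skip_invalid, dedup = dedup)
}

#' Write a peptide dataset to disk
#'
#' Inverse of [read_peptides()]; round-trips sequences and labels in order.
#'
#' @param x a `peptide_dataset`.
#' @param path output file.
#' @param dialect `"tabular"` (CSV) or `"fasta"` (label as last header token).
#' @return `path`, invisibly.
#' @export
write_peptides <- function(x, path, dialect = c("tabular", "fasta")) {
  stopifnot(inherits(x, "peptide_dataset"))
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    utils::write.csv(data.frame(sequence = x$sequence, label = x$label),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    lab <- ifelse(is.na(x$label), "NA", as.character(x$label))
    lines <- as.vector(rbind(sprintf(">pep%d|%s", seq_len(nrow(x)), lab),
                             x$sequence))
    writeLines(lines, path)
  }
  invisible(path)
}
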