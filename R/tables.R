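# Bundled amino-acid property machinery.
#
# Single-residue scales are taken from the AAindex database copy shipped with
# the seqinr package, so every lookup works offline and values are authentic
# database entries. Pair matrices (QSO distances) and the multi-scale lookup
# sets (contact-potential and quantum-topological stand-ins) are constructed
# from those scales; see the methods vignette for provenance notes.

# the 11 AAindex propensity scales of the physicochemical profile encoder (F1)
PHYSCHEM_IDS <- c("MEEJ800102", "WOLS870102", "CASG920101", "NAKH900110",
                  "FASG760105", "FAUJ880105", "CHAM830107", "QIAN880127",
                  "RACS820108", "DIGM050101", "TANS770109")

# the 8 conventional AAindex scales used by autocorrelation descriptor suites
AUTOCORR_IDS <- c("CIDH920105", "BHAR880101", "CHAM820101", "CHAM820102",
                  "CHOC760101", "BIGC670101", "CHAM810101", "DAYM780201")

# hydrophobicity / hydrophilicity scales for PseAA-family encoders
HYDROPHOBICITY_ID <- "KYTJ820101"
HYDROPHILICITY_ID <- "HOPT810101"

# 40 complete AAindex scales standing in for the contact-potential table set
# (F6); an evenly spaced draw over the complete-entry accessions, frozen here.
# Replaceable via the `aapp` argument of encoder_context().
AAPP_IDS <- c("ANDN920101", "AURR980110", "BASU050102", "BUNA790101",
              "CHAM830104", "CHOP780205", "CIDH920102", "COWR900101",
              "FASG760101", "FAUJ880109", "FUKS010103", "GEIM800103",
              "GEOR030105", "HOPA770101", "JANJ780101", "KANM800102",
              "KRIW790101", "LEVM760105", "MANP780101", "MEIH800103",
              "MUNV940103", "NAKH900101", "NAKH920102", "OOBM770101",
              "PALJ810104", "PARJ860101", "PONP930101", "QIAN880102",
              "QIAN880115", "QIAN880129", "RACS770103", "RACS820114",
              "RICJ880105", "ROBB760101", "ROBB790101", "SUYM030101",
              "TSAJ990102", "WERD780101", "WOLS870103", "ZIMJ680105")

# 21 scales standing in for the quantum-topological descriptor table (F7);
# same construction, replaceable via the `qtms` argument of encoder_context().
QTMS_IDS <- c("ARGP820101", "BASU050101", "CHAM830103", "CHOP780216",
              "EISD860102", "FODM020101", "GEOR030101", "ISOY800105",
              "KIDA850101", "LEVM780105", "MIYS990104", "NAKH900107",
              "OOBM850102", "PONP800101", "QIAN880106", "QIAN880132",
              "RADA880103", "ROBB760103", "SWER830101", "WERD780102",
              "ZIMJ680104")

# package-local cache for the seqinr AAindex copy
.tables_env <- new.env(parent = emptyenv())

aaindex_db <- function() {
  if (is.null(.tables_env$aaindex)) {
    e <- new.env()
    utils::data("aaindex", package = "seqinr", envir = e)
    db <- e$aaindex
    names(db) <- vapply(db, function(x) x$H, character(1))
    .tables_env$aaindex <- db
  }
  .tables_env$aaindex
}

#' Look up an amino-acid property table by AAindex accession
#'
#' Returns the 20 per-residue values of an AAindex entry as a named vector
#' over [AA_ALPHABET]. Errors on unknown accessions and on entries with
#' missing values, so downstream encoders always see complete tables.
#'
#' @param table_id AAindex accession, e.g. `"FAUJ880105"`.
#' @return named numeric vector of length 20 (names = one-letter codes,
#'   alphabetical order), with attribute `table_id`.
#' @examples
#' aa_property_table("FAUJ880105")
#' @export
aa_property_table <- function(table_id) {
  db <- aaindex_db()
  if (!table_id %in% names(db)) stop("unknown AAindex accession: ", table_id)
  vals <- db[[table_id]]$I
  one <- vapply(names(vals), function(n) seqinr::a(n), character(1))
  out <- as.numeric(vals)[match(AA_ALPHABET, one)]
  names(out) <- AA_ALPHABET
  if (anyNA(out)) stop("incomplete property table: ", table_id)
  attr(out, "table_id") <- table_id
  out
}

#' Write / read a property table as plain text
#'
#' Two-column whitespace-separated text (`letter value`), values printed with
#' 17 significant digits so the round trip is bit-identical.
#'
#' @param tab named numeric 20-vector as from [aa_property_table()].
#' @param path file path.
#' @return `write_property_table`: `path` invisibly; `read_property_table`:
#'   the table.
#' @export
write_property_table <- function(tab, path) {
  stopifnot(length(tab) == 20L, identical(names(tab), AA_ALPHABET))
  id <- attr(tab, "table_id")
  lines <- c(sprintf("# table_id: %s", if (is.null(id)) "custom" else id),
             sprintf("%s %s", names(tab), sprintf("%.17g", unname(tab))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_property_table
#' @export
read_property_table <- function(path) {
  lines <- readLines(path)
  id <- sub("^# table_id: ", "", lines[1])
  body <- read.table(text = lines[-1], col.names = c("letter", "value"),
                     stringsAsFactors = FALSE)
  if (nrow(body) != 20L || !setequal(body$letter, AA_ALPHABET))
    stop("incomplete property table in ", path)
  out <- body$value[match(AA_ALPHABET, body$letter)]
  names(out) <- AA_ALPHABET
  if (!identical(id, "custom")) attr(out, "table_id") <- id
  out
}

# standardize a scale to zero mean / unit (sample) SD over the 20 letters
standardize_scale <- function(tab) {
  s <- stats::sd(tab)
  if (s == 0) stop("zero-variance property scale")
  out <- (tab - mean(tab)) / s
  attributes(out) <- attributes(tab)
  out
}

# matrix of scales, one column per accession, rows = AA_ALPHABET
scale_matrix <- function(ids, standardize = FALSE) {
  m <- vapply(ids, function(id) {
    t <- aa_property_table(id)
    if (standardize) t <- standardize_scale(t)
    as.numeric(t)
  }, numeric(20L))
  rownames(m) <- AA_ALPHABET
  m
}

#' Grantham chemical distance matrix
#'
#' Reconstructs Grantham's 20x20 amino-acid difference matrix from his
#' published composition, polarity and volume properties (AAindex accessions
#' GRAR740101/2/3) with the original weighting
#' \eqn{D = \rho\sqrt{1.833\,\Delta c^2 + 0.1018\,\Delta p^2 + 0.000399\,\Delta v^2}}
#' and \eqn{\rho} fixed so the mean off-diagonal distance is 100.
#'
#' @return symmetric nonnegative 20x20 matrix with zero diagonal.
#' @export
grantham_distance <- function() {
  if (!is.null(.tables_env$grantham)) return(.tables_env$grantham)
  comp <- aa_property_table("GRAR740101")
  pol  <- aa_property_table("GRAR740102")
  vol  <- aa_property_table("GRAR740103")
  d <- sqrt(1.833 * outer(comp, comp, "-")^2 +
            0.1018 * outer(pol, pol, "-")^2 +
            0.000399 * outer(vol, vol, "-")^2)
  d <- d * 100 / mean(d[upper.tri(d)])
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  .tables_env$grantham <- d
  d
}

#' Physicochemical distance matrix
#'
#' The second distance matrix of the quasi-sequence-order encoder: Euclidean
#' distance over standardized hydrophobicity (KYTJ820101), hydrophilicity
#' (HOPT810101) and side-chain mass. This is a documented in-package
#' construction in the style of the classical physicochemical distance used
#' with quasi-sequence-order descriptors, not a copy of any published matrix.
#'
#' @return symmetric nonnegative 20x20 matrix with zero diagonal.
#' @export
physchem_distance <- function() {
  if (!is.null(.tables_env$physchem)) return(.tables_env$physchem)
  feats <- cbind(standardize_scale(aa_property_table(HYDROPHOBICITY_ID)),
                 standardize_scale(aa_property_table(HYDROPHILICITY_ID)),
                 standardize_scale(side_chain_mass()))
  d <- as.matrix(stats::dist(feats))
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  .tables_env$physchem <- d
  d
}

#' Amino-acid side-chain masses
#'
#' Monoisotopic-style side-chain (R-group) masses in Daltons, the third scale
#' of the pseudo amino-acid composition encoder.
#'
#' @return named numeric 20-vector over [AA_ALPHABET].
#' @export
side_chain_mass <- function() {
  m <- c(A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0,
         G = 1.0,  H = 82.0, I = 57.0, K = 73.0, L = 57.0,
         M = 75.0, N = 58.0, P = 42.0, Q = 72.0, R = 101.0,
         S = 31.0, T = 45.0, V = 43.0, W = 130.0, Y = 107.0)
  m[AA_ALPHABET]
}

# ---- CTD attribute partitions ----------------------------------------------

#' Standard CTD attribute partitions
#'
#' The seven conventional physicochemical attributes used by the
#' composition/transition/distribution (CTD) descriptors, each dividing the
#' 20 amino acids into three groups (Dubchak-style partitions).
#'
#' @return named list of 7 integer vectors (values 1/2/3 indexed by letter).
#' @export
ctd_attributes <- function() {
  grp <- function(g1, g2, g3) {
    v <- integer(20); names(v) <- AA_ALPHABET
    v[strsplit(g1, "")[[1]]] <- 1L
    v[strsplit(g2, "")[[1]]] <- 2L
    v[strsplit(g3, "")[[1]]] <- 3L
    stopifnot(all(v %in% 1:3))
    v
  }
  list(
    hydrophobicity   = grp("RKEDQN", "GASTPHY", "CLVIMFW"),
    vdw_volume       = grp("GASTPDC", "NVEQIL", "MHKFRYW"),
    polarity         = grp("LIFWCMVY", "PATGS", "HQRKNED"),
    polarizability   = grp("GASDT", "CPNVEQIL", "KMHFRYW"),
    charge           = grp("KR", "ANCQGHILMFPSTWYV", "DE"),
    secondary_struct = grp("EALMQKRH", "VIYCWFT", "GNPSD"),
    solvent_access   = grp("ALFCGIVW", "RKQEND", "MSPTHY")
  )
}

# ---- multi-scale lookup sets (F6 / F7) -------------------------------------

#' Contact-potential and quantum-topological lookup tables
#'
#' `aapp_tables()` returns the 20x40 per-residue lookup matrix behind the
#' amino-acid pairwise contact potential encoder (F6); `qtms_table()` the
#' 20x21 matrix behind the quantum-topological descriptor encoder (F7).
#' The package defaults are reconstructions assembled from complete AAindex
#' scales (accession lists `AAPP_IDS`, `QTMS_IDS`); supply your own matrix
#' (rows = [AA_ALPHABET]) to use source descriptor values.
#'
#' @param custom optional replacement matrix with 20 rows named by
#'   [AA_ALPHABET] and 40 (AAPP) or 21 (QTMS) columns.
#' @return numeric matrix, rows = amino acids.
#' @export
aapp_tables <- function(custom = NULL) {
  if (!is.null(custom)) {
    check_lookup(custom, 40L, "aapp")
    return(custom)
  }
  if (is.null(.tables_env$aapp)) .tables_env$aapp <- scale_matrix(AAPP_IDS)
  .tables_env$aapp
}

#' @rdname aapp_tables
#' @export
qtms_table <- function(custom = NULL) {
  if (!is.null(custom)) {
    check_lookup(custom, 21L, "qtms")
    return(custom)
  }
  if (is.null(.tables_env$qtms)) .tables_env$qtms <- scale_matrix(QTMS_IDS)
  .tables_env$qtms
}

check_lookup <- function(m, ncol_expect, what) {
  if (!is.matrix(m) || nrow(m) != 20L || ncol(m) != ncol_expect ||
      !identical(rownames(m), AA_ALPHABET) || anyNA(m))
    stop(sprintf("%s table must be a complete 20x%d matrix with rows %s",
                 what, ncol_expect, paste(AA_ALPHABET, collapse = "")))
  invisible(m)
}
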