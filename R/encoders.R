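# The 18 sequence-derived feature encoders (F1-F18).
#
# Every encoder maps one validated 9-mer to a fixed-length numeric vector;
# encode_features() applies a set of encoders to a whole dataset and returns
# row-aligned feature blocks. Encoders that need fitted context (the
# Smith-Waterman similarity profile, which scores against the training
# sequences) or external annotations (RASA / secondary structure) read them
# from an encoder_context.

#' Catalog of the 18 feature encoders
#'
#' One row per encoder: identifier (`F1`..`F18`), short name, whether the
#' encoder takes a lag/order parameter lambda, its default lambda (the
#' best-performing values for lag-parameterized encoders), and whether it
#' requires a fitted reference (`F5`) or structure annotations (`F17`/`F18`).
#'
#' @return a data frame with columns `id`, `name`, `has_lambda`,
#'   `default_lambda`, `requires_fit`, `requires_annotator`.
#' @export
feature_catalog <- function() {
  data.frame(
    id = paste0("F", 1:18),
    name = c("physicochemical propensities", "amino acid composition",
             "amino acid pair profile", "sparse profile",
             "pairwise similarity profile", "contact potentials (AAPP)",
             "quantum-topological descriptors (QTMS)",
             "CTD composition", "CTD transition", "CTD distribution",
             "Moran autocorrelation", "Geary autocorrelation",
             "Moreau-Broto autocorrelation", "quasi-sequence-order",
             "pseudo amino acid composition",
             "amphiphilic pseudo amino acid composition",
             "predicted RASA", "predicted secondary structure"),
    has_lambda = c(rep(FALSE, 10), rep(TRUE, 6), FALSE, FALSE),
    default_lambda = c(rep(NA_integer_, 10), 7L, 7L, 7L, 8L, 8L, 2L,
                       NA_integer_, NA_integer_),
    requires_fit = c(rep(FALSE, 4), TRUE, rep(FALSE, 13)),
    requires_annotator = c(rep(FALSE, 16), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Expected encoder output dimension
#'
#' Dimension of each encoder's vector for a 9-mer: F1 99, F2 20, F3 400,
#' F4 180 (nine 20-bit one-hot blocks), F5 the reference-set size `n_ref`,
#' F6 360, F7 189, F8/F9 21, F10 105, F11-F13 `8*lambda`, F14 `40+2*lambda`,
#' F15 `20+lambda`, F16 `20+2*lambda`, F17 9, F18 27.
#'
#' @param id encoder identifier `"F1"`..`"F18"`.
#' @param lambda lag/order parameter (1..8) for F11-F16.
#' @param n_ref reference-set size, needed for F5 only.
#' @return integer dimension.
#' @export
feature_dim <- function(id, lambda = NULL, n_ref = NA_integer_) {
  if (is.null(lambda) || is.na(lambda)) lambda <- NULL else check_lambda(lambda)
  switch(id,
    F1 = 99L, F2 = 20L, F3 = 400L, F4 = 180L,
    F5 = as.integer(n_ref),
    F6 = 360L, F7 = 189L, F8 = 21L, F9 = 21L, F10 = 105L,
    F11 = , F12 = , F13 = 8L * need_lambda(lambda, id),
    F14 = 40L + 2L * need_lambda(lambda, id),
    F15 = 20L + need_lambda(lambda, id),
    F16 = 20L + 2L * need_lambda(lambda, id),
    F17 = 9L, F18 = 27L,
    stop("unknown encoder id: ", id)
  )
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda != round(lambda) ||
      lambda < 1 || lambda > PEPTIDE_LENGTH - 1L)
    stop("lambda must be an integer in 1..", PEPTIDE_LENGTH - 1L)
  as.integer(lambda)
}

need_lambda <- function(lambda, id) {
  if (is.null(lambda) || is.na(lambda))
    stop("encoder ", id, " needs a lambda parameter")
  check_lambda(lambda)
}

aa_index <- function(sequence) {
  idx <- match(pep_chars(sequence), AA_ALPHABET)
  if (anyNA(idx)) stop("non-standard residue in '", sequence, "'")
  idx
}

# ---- composition-style encoders --------------------------------------------

#' Amino acid composition (F2)
#'
#' Fraction of each of the 20 amino acids in the peptide; sums to 1.
#'
#' @param sequence a 9-mer peptide sequence.
#' @return numeric 20-vector named by [AA_ALPHABET].
#' @export
encode_aac <- function(sequence) {
  v <- tabulate(aa_index(sequence), 20L) / PEPTIDE_LENGTH
  names(v) <- AA_ALPHABET
  v
}

#' Amino acid pair profile (F3)
#'
#' Fraction of each ordered adjacent residue pair among the 8 adjacent pairs;
#' 400 dimensions (first residue major), sums to 1.
#'
#' @inheritParams encode_aac
#' @return numeric 400-vector named by residue pairs.
#' @export
encode_dipeptide <- function(sequence) {
  idx <- aa_index(sequence)
  n <- length(idx)
  pair <- (idx[-n] - 1L) * 20L + idx[-1L]
  v <- tabulate(pair, 400L) / (n - 1L)
  names(v) <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  v
}

#' Sparse one-hot profile (F4)
#'
#' Each residue becomes a 20-bit one-hot block; blocks are concatenated in
#' sequence order into a 180-vector with exactly nine ones.
#'
#' @inheritParams encode_aac
#' @return numeric 180-vector.
#' @export
encode_sparse <- function(sequence) {
  idx <- aa_index(sequence)
  v <- numeric(20L * PEPTIDE_LENGTH)
  v[(seq_along(idx) - 1L) * 20L + idx] <- 1
  v
}

#' Physicochemical propensity profile (F1)
#'
#' Position-major concatenation of 11 AAindex propensity values per residue
#' (9 positions x 11 scales = 99 dimensions).
#'
#' @inheritParams encode_aac
#' @param ids AAindex accessions of the 11 scales (default `PHYSCHEM_IDS`).
#' @return numeric 99-vector.
#' @export
encode_physchem <- function(sequence, ids = PHYSCHEM_IDS) {
  m <- scale_matrix(ids)
  as.vector(t(m[aa_index(sequence), , drop = FALSE]))
}

#' Contact-potential profile (F6)
#'
#' Position-major per-residue values under the 40 contact-potential lookup
#' tables (9 x 40 = 360 dimensions). See [aapp_tables()] for the default
#' table set and how to supply source values.
#'
#' @inheritParams encode_aac
#' @param tables 20x40 lookup matrix (default [aapp_tables()]).
#' @return numeric 360-vector.
#' @export
encode_aapp <- function(sequence, tables = aapp_tables()) {
  check_lookup(tables, 40L, "aapp")
  as.vector(t(tables[aa_index(sequence), , drop = FALSE]))
}

#' Quantum-topological descriptor profile (F7)
#'
#' Position-major per-residue values under the 21 descriptor columns
#' (9 x 21 = 189 dimensions). See [qtms_table()].
#'
#' @inheritParams encode_aac
#' @param table 20x21 lookup matrix (default [qtms_table()]).
#' @return numeric 189-vector.
#' @export
encode_qtms <- function(sequence, table = qtms_table()) {
  check_lookup(table, 21L, "qtms")
  as.vector(t(table[aa_index(sequence), , drop = FALSE]))
}

# ---- CTD (F8/F9/F10) -------------------------------------------------------

#' Composition / transition / distribution descriptors (F8-F10)
#'
#' For each of the 7 standard attribute partitions ([ctd_attributes()]):
#' `C` - the fraction of residues falling in each of the 3 groups (21 dims);
#' `T` - the count of adjacent residue pairs whose groups differ, per
#' unordered group pair, divided by 8 (21 dims); `D` - for each group, the
#' sequence positions (as percent of length) of its first, 25\%, 50\%, 75\%
#' and last occurrence, 0 when the group is absent (105 dims).
#'
#' @inheritParams encode_aac
#' @param part which descriptor: `"C"`, `"T"` or `"D"`.
#' @return numeric vector of length 21, 21 or 105.
#' @export
encode_ctd <- function(sequence, part = c("C", "T", "D")) {
  part <- match.arg(part)
  idx <- aa_index(sequence)
  attrs <- ctd_attributes()
  out <- lapply(attrs, function(grp) {
    g <- grp[idx]
    if (part == "C") {
      tabulate(g, 3L) / length(g)
    } else if (part == "T") {
      a <- g[-length(g)]; b <- g[-1L]
      keep <- a != b
      lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]
      # unordered distinct pairs mapped (1,2)->1, (1,3)->2, (2,3)->3
      tabulate(lo + hi - 2L, 3L) / (length(g) - 1L)
    } else {
      unlist(lapply(1:3, function(k) {
        pos <- which(g == k)
        if (length(pos) == 0L) return(numeric(5L))
        n <- length(pos)
        picks <- pos[c(1L, ceiling(0.25 * n), ceiling(0.5 * n),
                       ceiling(0.75 * n), n)]
        100 * picks / length(g)
      }))
    }
  })
  unlist(out, use.names = FALSE)
}

# ---- autocorrelation (F11/F12/F13) -----------------------------------------

#' Property autocorrelation descriptors (F11-F13)
#'
#' Autocorrelation of 8 standardized AAindex property scales along the
#' sequence, for lags 1..lambda (property-major ordering, `8*lambda` dims).
#' With residue values \eqn{P_1..P_N} (N = 9) at lag d:
#' Moreau-Broto \eqn{AC(d) = \sum_{i=1}^{N-d} P_i P_{i+d} / (N-d)};
#' Moran \eqn{I(d) = [\sum (P_i-\bar P)(P_{i+d}-\bar P)/(N-d)] /
#' [\sum (P_i-\bar P)^2 / N]};
#' Geary \eqn{C(d) = [\sum (P_i-P_{i+d})^2 / (2(N-d))] /
#' [\sum (P_i-\bar P)^2 / (N-1)]}.
#' Scales are standardized to zero mean / unit SD over the 20 letters before
#' use. On a zero-variance profile (homopolymer) the Moran and Geary
#' denominators vanish; the affected entries are set to 0 with a warning.
#'
#' @inheritParams encode_aac
#' @param kind `"moran"`, `"geary"` or `"moreau_broto"`.
#' @param lambda maximum lag, 1..8.
#' @param ids AAindex accessions of the 8 property scales.
#' @return numeric vector of length `8*lambda`.
#' @export
encode_autocorrelation <- function(sequence,
                                   kind = c("moran", "geary", "moreau_broto"),
                                   lambda = 7L, ids = AUTOCORR_IDS) {
  kind <- match.arg(kind)
  lambda <- check_lambda(lambda)
  idx <- aa_index(sequence)
  n <- length(idx)
  props <- scale_matrix(ids, standardize = TRUE)
  out <- numeric(0)
  for (j in seq_len(ncol(props))) {
    p <- props[idx, j]
    pbar <- mean(p)
    dev2 <- sum((p - pbar)^2)
    vals <- numeric(lambda)
    for (d in seq_len(lambda)) {
      i <- seq_len(n - d)
      vals[d] <- switch(kind,
        moreau_broto = sum(p[i] * p[i + d]) / (n - d),
        moran = {
          if (dev2 == 0) { warning("zero-variance profile; Moran set to 0"); 0
          } else (sum((p[i] - pbar) * (p[i + d] - pbar)) / (n - d)) / (dev2 / n)
        },
        geary = {
          if (dev2 == 0) { warning("zero-variance profile; Geary set to 0"); 0
          } else (sum((p[i] - p[i + d])^2) / (2 * (n - d))) / (dev2 / (n - 1))
        })
    }
    out <- c(out, vals)
  }
  out
}

# ---- sequence-order encoders (F14/F15/F16) ---------------------------------

#' Quasi-sequence-order descriptors (F14)
#'
#' For each of two 20x20 amino-acid distance matrices (Grantham chemical
#' distance and the package physicochemical distance), sequence-order
#' coupling numbers \eqn{\tau_d = \sum_{i=1}^{N-d} d(r_i, r_{i+d})^2} for
#' d = 1..lambda are combined with the residue counts \eqn{f_a}:
#' the first 20 entries of each block are \eqn{f_a/(\sum f + w\sum\tau)}, the
#' next lambda entries \eqn{w\tau_d/(\sum f + w\sum\tau)}. The two blocks of
#' length `20+lambda` are concatenated (`40+2*lambda` dims); each block sums
#' to 1.
#'
#' @inheritParams encode_aac
#' @param lambda number of sequence-order coupling terms, 1..8.
#' @param w weight of the sequence-order terms (default 0.1).
#' @param dists list of two symmetric nonnegative 20x20 distance matrices.
#' @return numeric vector of length `40+2*lambda`.
#' @export
encode_qso <- function(sequence, lambda = 8L, w = 0.1,
                       dists = list(grantham_distance(), physchem_distance())) {
  lambda <- check_lambda(lambda)
  stopifnot(length(dists) == 2L)
  idx <- aa_index(sequence)
  n <- length(idx)
  f <- tabulate(idx, 20L)
  unlist(lapply(dists, function(D) {
    stopifnot(is.matrix(D), dim(D) == c(20L, 20L))
    tau <- vapply(seq_len(lambda), function(d) {
      i <- seq_len(n - d)
      sum(D[cbind(idx[i], idx[i + d])]^2)
    }, numeric(1))
    denom <- sum(f) + w * sum(tau)
    c(f / denom, w * tau / denom)
  }), use.names = FALSE)
}

pseaa_scales <- function() {
  cbind(h1 = standardize_scale(aa_property_table(HYDROPHOBICITY_ID)),
        h2 = standardize_scale(aa_property_table(HYDROPHILICITY_ID)),
        m  = standardize_scale(side_chain_mass()))
}

#' Pseudo amino-acid composition (F15) and amphiphilic variant (F16)
#'
#' `encode_pseaa`: sequence-order factors
#' \eqn{\theta_d = \frac{1}{N-d}\sum_i \Theta(r_i, r_{i+d})} where
#' \eqn{\Theta} is the mean squared difference of three standardized scales
#' (hydrophobicity, hydrophilicity, side-chain mass); output entries 1..20
#' are \eqn{f_a/(\sum f + w\sum\theta)} and entries 21..20+lambda are
#' \eqn{w\theta_d/(\sum f + w\sum\theta)} (`20+lambda` dims, sums to 1).
#'
#' `encode_ampseaa`: per lag d two amphiphilic correlation factors, the mean
#' products of standardized hydrophobicity values
#' (\eqn{\tau_{2d-1}}) and of standardized hydrophilicity values
#' (\eqn{\tau_{2d}}); entries 21..20+2*lambda are
#' \eqn{w\tau_k/(\sum f + w\sum\tau)} (`20+2*lambda` dims, sums to 1).
#'
#' @inheritParams encode_aac
#' @param lambda number of sequence-order factors, 1..8.
#' @param w sequence-order weight (default 0.05).
#' @return numeric vector of length `20+lambda` / `20+2*lambda`.
#' @export
encode_pseaa <- function(sequence, lambda = 8L, w = 0.05) {
  lambda <- check_lambda(lambda)
  idx <- aa_index(sequence)
  n <- length(idx)
  sc <- pseaa_scales()
  f <- tabulate(idx, 20L)
  theta <- vapply(seq_len(lambda), function(d) {
    i <- seq_len(n - d)
    mean(rowMeans((sc[idx[i], , drop = FALSE] -
                   sc[idx[i + d], , drop = FALSE])^2))
  }, numeric(1))
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

#' @rdname encode_pseaa
#' @export
encode_ampseaa <- function(sequence, lambda = 2L, w = 0.05) {
  lambda <- check_lambda(lambda)
  idx <- aa_index(sequence)
  n <- length(idx)
  sc <- pseaa_scales()
  f <- tabulate(idx, 20L)
  tau <- numeric(2L * lambda)
  for (d in seq_len(lambda)) {
    i <- seq_len(n - d)
    tau[2L * d - 1L] <- mean(sc[idx[i], "h1"] * sc[idx[i + d], "h1"])
    tau[2L * d]      <- mean(sc[idx[i], "h2"] * sc[idx[i + d], "h2"])
  }
  denom <- sum(f) + w * sum(tau)
  c(f / denom, w * tau / denom)
}

# ---- structure encoders (F17/F18) ------------------------------------------

#' Predicted-structure encoders (F17/F18)
#'
#' `"rasa"`: the 9 per-residue predicted relative accessible surface areas.
#' `"ss"`: the 9 secondary-structure labels one-hot encoded as H = (1,0,0),
#' E = (0,1,0), C = (0,0,1) and concatenated (27 dims, exactly nine ones).
#'
#' @inheritParams encode_aac
#' @param annotation a structure annotation as returned by
#'   [annotate_structure()].
#' @param part `"rasa"` or `"ss"`.
#' @return numeric vector of length 9 or 27.
#' @export
encode_structure <- function(sequence, annotation, part = c("rasa", "ss")) {
  part <- match.arg(part)
  if (length(annotation$rasa) != PEPTIDE_LENGTH ||
      length(annotation$ss) != PEPTIDE_LENGTH)
    stop("annotation length mismatch")
  if (part == "rasa") return(as.numeric(annotation$rasa))
  k <- match(annotation$ss, c("H", "E", "C"))
  if (anyNA(k)) stop("secondary-structure labels must be H/E/C")
  v <- numeric(27L)
  v[(seq_len(PEPTIDE_LENGTH) - 1L) * 3L + k] <- 1
  v
}

# ---- dataset-level encoding ------------------------------------------------

#' Encoder context: fitted references, annotators and lookup tables
#'
#' Bundles everything encoders may need beyond the sequence itself: the
#' training reference for the similarity profile (F5), the structure
#' annotator (F17/F18), replacement lookup tables, and the sequence-order
#' weights.
#'
#' @param train a `peptide_dataset` whose sequences become the similarity
#'   reference (required only when encoding F5).
#' @param annotator a `structure_annotator` (default [surrogate_annotator()]).
#' @param aapp,qtms optional replacement lookup matrices (see
#'   [aapp_tables()]).
#' @param qso_w,pseaa_w sequence-order weights for F14 and F15/F16.
#' @return an object of class `encoder_context`.
#' @export
encoder_context <- function(train = NULL, annotator = surrogate_annotator(),
                            aapp = NULL, qtms = NULL,
                            qso_w = 0.1, pseaa_w = 0.05) {
  ref <- if (!is.null(train)) fit_similarity_reference(train) else NULL
  structure(list(ref = ref, annotator = annotator,
                 aapp = aapp_tables(aapp), qtms = qtms_table(qtms),
                 qso_w = qso_w, pseaa_w = pseaa_w),
            class = "encoder_context")
}

resolve_lambda <- function(features, lambda) {
  cat_ <- feature_catalog()
  def <- stats::setNames(cat_$default_lambda, cat_$id)
  out <- def[features]
  if (!is.null(lambda)) {
    if (is.null(names(lambda))) {
      out[cat_$has_lambda[match(features, cat_$id)]] <- as.integer(lambda)
    } else {
      out[names(lambda)] <- as.integer(lambda)
    }
  }
  out
}

encode_one <- function(sequence, id, lambda, ctx) {
  switch(id,
    F1 = encode_physchem(sequence),
    F2 = encode_aac(sequence),
    F3 = encode_dipeptide(sequence),
    F4 = encode_sparse(sequence),
    F6 = encode_aapp(sequence, ctx$aapp),
    F7 = encode_qtms(sequence, ctx$qtms),
    F8 = encode_ctd(sequence, "C"),
    F9 = encode_ctd(sequence, "T"),
    F10 = encode_ctd(sequence, "D"),
    F11 = encode_autocorrelation(sequence, "moran", lambda),
    F12 = encode_autocorrelation(sequence, "geary", lambda),
    F13 = encode_autocorrelation(sequence, "moreau_broto", lambda),
    F14 = encode_qso(sequence, lambda, ctx$qso_w),
    F15 = encode_pseaa(sequence, lambda, ctx$pseaa_w),
    F16 = encode_ampseaa(sequence, lambda, ctx$pseaa_w),
    F17 = encode_structure(sequence,
                           annotate_structure(ctx$annotator, sequence), "rasa"),
    F18 = encode_structure(sequence,
                           annotate_structure(ctx$annotator, sequence), "ss"),
    stop("unknown encoder id: ", id)
  )
}

#' Encode a dataset into per-feature blocks
#'
#' Applies the requested encoders to every peptide and returns one numeric
#' matrix per encoder, rows aligned with the dataset across all blocks.
#'
#' @param x a `peptide_dataset` or character vector of 9-mers.
#' @param features encoder ids, e.g. `c("F2", "F14")` (default all 18).
#' @param lambda `NULL` for per-encoder defaults; a single integer applied to
#'   all lag-parameterized encoders; or a named vector like `c(F14 = 8)`.
#' @param context an [encoder_context()]; required for F5 (fitted reference)
#'   and used by F6/F7/F17/F18.
#' @return named list of matrices (one per encoder id), each with `nrow(x)`
#'   rows and [feature_dim()] columns.
#' @examples
#' ds <- synth_peptides(5, 5, seed = 1)
#' blocks <- encode_features(ds, c("F2", "F8"))
#' sapply(blocks, dim)
#' @export
encode_features <- function(x, features = feature_catalog()$id, lambda = NULL,
                            context = encoder_context()) {
  seqs <- if (inherits(x, "peptide_dataset")) x$sequence else toupper(x)
  bad <- validate_peptides(seqs)
  if (any(!is.na(bad))) stop("invalid peptide(s): ",
                             paste(seqs[!is.na(bad)], collapse = ", "))
  lam <- resolve_lambda(features, lambda)
  blocks <- lapply(features, function(id) {
    if (id == "F5") {
      if (is.null(context$ref))
        stop("F5 requires an encoder_context with a fitted training reference")
      m <- similarity_scores(seqs, context$ref)
    } else {
      m <- t(vapply(seqs, encode_one, id = id, lambda = lam[[id]], ctx = context,
                    FUN.VALUE = numeric(feature_dim(id, lam[[id]]))))
    }
    rownames(m) <- NULL
    if (!all(is.finite(m))) stop("non-finite entries in block ", id)
    m
  })
  names(blocks) <- features
  blocks
}
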