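# Brute-force reference implementations used as independent oracles.
# Each is a literal translation of the defining formula, sharing no code
# with the package implementation it checks.

random_peptides <- function(n, seed) {
  set.seed(seed)
  replicate(n, paste(sample(AA_ALPHABET, PEPTIDE_LENGTH, replace = TRUE),
                     collapse = ""))
}

# AUC by exhaustive positive/negative pair comparison
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

oracle_standardize <- function(v) (v - mean(v)) / sd(v)

# property values of a peptide under a standardized AAindex scale
.pvals <- function(sequence, id) {
  tab <- oracle_standardize(aa_property_table(id))
  tab[strsplit(sequence, "")[[1]]]
}

oracle_moreau_broto <- function(sequence, lambda, ids = AUTOCORR_IDS) {
  out <- c()
  for (id in ids) {
    p <- .pvals(sequence, id); n <- length(p)
    for (d in 1:lambda) {
      s <- 0
      for (i in 1:(n - d)) s <- s + p[i] * p[i + d]
      out <- c(out, s / (n - d))
    }
  }
  unname(out)
}

oracle_moran <- function(sequence, lambda, ids = AUTOCORR_IDS) {
  out <- c()
  for (id in ids) {
    p <- .pvals(sequence, id); n <- length(p); pb <- mean(p)
    den <- sum((p - pb)^2) / n
    for (d in 1:lambda) {
      s <- 0
      for (i in 1:(n - d)) s <- s + (p[i] - pb) * (p[i + d] - pb)
      out <- c(out, (s / (n - d)) / den)
    }
  }
  unname(out)
}

oracle_geary <- function(sequence, lambda, ids = AUTOCORR_IDS) {
  out <- c()
  for (id in ids) {
    p <- .pvals(sequence, id); n <- length(p)
    den <- sum((p - mean(p))^2) / (n - 1)
    for (d in 1:lambda) {
      s <- 0
      for (i in 1:(n - d)) s <- s + (p[i] - p[i + d])^2
      out <- c(out, (s / (2 * (n - d))) / den)
    }
  }
  unname(out)
}

oracle_qso <- function(sequence, lambda, w = 0.1) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  f <- sapply(AA_ALPHABET, function(a) sum(ch == a))
  out <- c()
  for (D in list(grantham_distance(), physchem_distance())) {
    tau <- numeric(lambda)
    for (d in 1:lambda) {
      s <- 0
      for (i in 1:(n - d)) s <- s + D[ch[i], ch[i + d]]^2
      tau[d] <- s
    }
    den <- sum(f) + w * sum(tau)
    out <- c(out, f / den, w * tau / den)
  }
  unname(out)
}

oracle_pseaa <- function(sequence, lambda, w = 0.05) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  h1 <- oracle_standardize(aa_property_table("KYTJ820101"))
  h2 <- oracle_standardize(aa_property_table("HOPT810101"))
  m <- oracle_standardize(side_chain_mass())
  f <- sapply(AA_ALPHABET, function(a) sum(ch == a))
  theta <- numeric(lambda)
  for (d in 1:lambda) {
    s <- 0
    for (i in 1:(n - d)) {
      a <- ch[i]; b <- ch[i + d]
      s <- s + ((h1[a] - h1[b])^2 + (h2[a] - h2[b])^2 + (m[a] - m[b])^2) / 3
    }
    theta[d] <- s / (n - d)
  }
  den <- sum(f) + w * sum(theta)
  unname(c(f / den, w * theta / den))
}

# Smith-Waterman with affine gaps: gap of length k costs open + k * ext
oracle_sw <- function(a, b, open = 10, ext = 1) {
  B <- epiGA:::blosum62()
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- E <- FF <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    FF[i, j] <- max(H[i - 1, j] - open - ext, FF[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + B[a[i - 1], b[j - 1]], E[i, j],
                   FF[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# small GA/CV configs shared across tests
tiny_control <- function(...) {
  args <- utils::modifyList(list(pop_size = 8L, max_generations = 4L,
                                 internal_folds = 3L, ntree = 40L),
                            list(...))
  do.call(ga_control, args)
}
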