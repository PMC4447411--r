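test_that("every encoder's dimension matches the catalog for all lags", {
  cat_ <- feature_catalog()
  ds <- synth_peptides(4, 4, seed = 21)
  ctx <- encoder_context(train = ds)
  fixed <- cat_$id[!cat_$has_lambda]
  blocks <- encode_features(ds, fixed, context = ctx)
  for (id in fixed) {
    expect_equal(ncol(blocks[[id]]),
                 feature_dim(id, n_ref = nrow(ds)), info = id)
    expect_equal(nrow(blocks[[id]]), nrow(ds), info = id)
  }
  for (id in cat_$id[cat_$has_lambda]) for (lam in 1:8) {
    b <- encode_features(ds$sequence[1], id, lambda = lam, context = ctx)
    expect_equal(ncol(b[[id]]), feature_dim(id, lam),
                 info = sprintf("%s lambda=%d", id, lam))
  }
  expect_error(encode_autocorrelation("ACDEFGHIK", "moran", lambda = 9),
               "lambda")
  expect_error(encode_qso("ACDEFGHIK", lambda = 0), "lambda")
})

test_that("composition encoders count residues and pairs correctly", {
  a <- encode_aac("AAAAAAAAA")
  expect_equal(unname(a["A"]), 1)
  expect_equal(sum(a), 1)
  b <- encode_aac("ACDEFGHIK")
  expect_equal(sort(unique(unname(b))), c(0, 1 / 9))
  expect_equal(sum(b > 0), 9L)

  d <- encode_dipeptide("ACACACACA")
  expect_equal(unname(d["AC"]), 4 / 8)
  expect_equal(unname(d["CA"]), 4 / 8)
  expect_equal(sum(d), 1)
  expect_equal(unname(encode_dipeptide("AAAAAAAAA")["AA"]), 1)

  s <- encode_sparse("AAAAAAAAA")
  expect_equal(which(s == 1), seq(1, 161, by = 20))
  s2 <- encode_sparse("ACDEFGHIK")
  expect_equal(sum(s2 == 1), 9L)
  expect_equal(sum(s2 == 0), 171L)
  # one substitution changes exactly two entries
  expect_equal(sum(encode_sparse("ACDEFGHIK") != encode_sparse("ACDEFGHIY")),
               2L)
})

test_that("profile encoders are position-major lookups", {
  v <- encode_physchem("LLLLLLLLL")
  expect_length(v, 99L)
  expect_equal(v, rep(v[1:11], 9))
  # swapping two residues permutes the per-position slices
  v1 <- encode_physchem("ACDEFGHIK")
  v2 <- encode_physchem("CADEFGHIK")
  expect_equal(v1[1:11], v2[12:22])
  expect_equal(v1[12:22], v2[1:11])
  expect_equal(v1[23:99], v2[23:99])

  p <- encode_aapp("LLLLLLLLL")
  expect_length(p, 360L)
  expect_equal(p, rep(p[1:40], 9))

  q1 <- encode_qtms("ACDEFGHIK")
  q2 <- encode_qtms("ACDEFGHIY")
  expect_length(q1, 189L)
  expect_equal(q1[1:168], q2[1:168])
  expect_false(identical(q1[169:189], q2[169:189]))
  expect_equal(encode_qtms("ACDEFGHIK",
                           matrix(0, 20, 21,
                                  dimnames = list(AA_ALPHABET, NULL))),
               rep(0, 189))
})

test_that("CTD fractions, transitions and distributions behave", {
  ch <- encode_ctd("ACDEFGHIK", "C")
  expect_length(ch, 21L)
  for (k in 1:7) expect_equal(sum(ch[(3 * k - 2):(3 * k)]), 1)
  # all residues in one hydrophobicity group -> no transitions there
  tr <- encode_ctd("LLVVIIMMF", "T")  # all hydrophobic (group 3)
  expect_equal(unname(tr[1:3]), c(0, 0, 0))
  expect_length(encode_ctd("ACDEFGHIK", "D"), 105L)
  # distribution of a homopolymer: group present at 1/9..9/9
  d <- encode_ctd("AAAAAAAAA", "D")
  expect_true(all(d[d > 0] <= 100))
})

test_that("autocorrelation encoders match their brute-force formulas", {
  for (s in random_peptides(7, seed = 31)) {
    expect_equal(encode_autocorrelation(s, "moreau_broto", 7),
                 oracle_moreau_broto(s, 7), tolerance = 1e-12)
    expect_equal(encode_autocorrelation(s, "moran", 5),
                 oracle_moran(s, 5), tolerance = 1e-12)
    expect_equal(encode_autocorrelation(s, "geary", 8),
                 oracle_geary(s, 8), tolerance = 1e-12)
  }
  # homopolymer: Moreau-Broto collapses to the squared standardized value
  z <- epiGA:::standardize_scale(aa_property_table(AUTOCORR_IDS[1]))
  mb <- encode_autocorrelation("WWWWWWWWW", "moreau_broto", 3)
  expect_equal(mb[1:3], rep(unname(z["W"])^2, 3))
  # zero-variance profile: Moran/Geary emit 0 with warnings (one per scale)
  w <- capture_warnings(m0 <- encode_autocorrelation("WWWWWWWWW", "moran", 2))
  expect_true(length(w) > 0 && all(grepl("zero-variance", w)))
  expect_equal(m0, rep(0, 16))
})

test_that("Geary at lag 1 separates alternating from constant profiles", {
  # alternating extreme-property residues vs homopolymer baseline
  tab <- epiGA:::standardize_scale(aa_property_table(AUTOCORR_IDS[1]))
  hi <- names(which.max(tab)); lo <- names(which.min(tab))
  alt <- paste(rep(c(hi, lo), length.out = 9), collapse = "")
  g_alt <- oracle_geary(alt, 1)[1]
  # near-constant permutation: same residues bunched together
  bunch <- paste(c(rep(hi, 5), rep(lo, 4)), collapse = "")
  g_bunch <- oracle_geary(bunch, 1)[1]
  expect_gt(g_alt, g_bunch)
  expect_equal(encode_autocorrelation(alt, "geary", 1)[1], g_alt,
               tolerance = 1e-12)
})

test_that("sequence-order encoders match oracles and normalize", {
  for (s in random_peptides(7, seed = 41)) {
    expect_equal(encode_qso(s, 8), oracle_qso(s, 8), tolerance = 1e-12)
    expect_equal(encode_pseaa(s, 8), oracle_pseaa(s, 8), tolerance = 1e-12)
  }
  s <- "ACDEFGHIK"
  q <- encode_qso(s, 5)
  expect_equal(sum(q[1:25]), 1)   # first matrix block
  expect_equal(sum(q[26:50]), 1)  # second matrix block
  expect_equal(sum(encode_pseaa(s, 4)), 1)
  expect_equal(sum(encode_ampseaa(s, 3)), 1)
  # w = 0 reduces heads to AAC and kills the tails
  expect_equal(encode_qso(s, 3, w = 0)[1:20], unname(encode_aac(s)))
  p0 <- encode_pseaa(s, 3, w = 0)
  expect_equal(p0[1:20], unname(encode_aac(s)))
  expect_equal(p0[21:23], rep(0, 3))
  a0 <- encode_ampseaa(s, 2, w = 0)
  expect_equal(a0[1:20], unname(encode_aac(s)))
  expect_equal(a0[21:24], rep(0, 4))
})

test_that("structure encoders produce RASA values and one-hot SS", {
  ann <- list(rasa = seq(10, 90, by = 10), ss = rep("H", 9))
  expect_equal(encode_structure("ACDEFGHIK", ann, "rasa"),
               seq(10, 90, by = 10))
  v <- encode_structure("ACDEFGHIK", ann, "ss")
  expect_equal(which(v == 1), seq(1, 25, by = 3))  # all-helix offsets
  ann$ss <- c("H", "E", "C", "H", "E", "C", "H", "E", "C")
  v2 <- encode_structure("ACDEFGHIK", ann, "ss")
  expect_equal(sum(v2), 9)
  expect_error(encode_structure("ACDEFGHIK",
                                list(rasa = 1:5, ss = rep("H", 9)), "rasa"),
               "length")
})

test_that("encoding is deterministic and row-aligned across blocks", {
  ds <- synth_peptides(6, 6, seed = 5)
  ctx <- encoder_context(train = ds)
  b1 <- encode_features(ds, c("F2", "F5", "F14"), context = ctx)
  b2 <- encode_features(ds, c("F2", "F5", "F14"), context = ctx)
  expect_identical(b1, b2)
  # row i of every block encodes peptide i
  i <- 4L
  single <- encode_features(ds$sequence[i], c("F2", "F14"), context = ctx)
  expect_equal(b1$F2[i, ], single$F2[1, ])
  expect_equal(b1$F14[i, ], single$F14[1, ])
  expect_named(encode_features(ds, character(0), context = ctx),
               character(0))
})
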