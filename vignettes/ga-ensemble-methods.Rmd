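---
title: "Methods: GA-selected ensembles for epitope immunogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-selected ensembles for epitope immunogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiGA)
```

## The model

`epiGA` classifies HLA-A2 restricted 9-mer peptides as immunogenic or not
from sequence alone. The model has three layers:

1. **Feature encoders.** Eighteen encoders F1–F18 map a peptide to a
   fixed-length numeric vector (see `feature_catalog()`): composition-type
   profiles (F2 amino-acid composition, F3 dipeptide profile, F8–F10 CTD),
   per-position lookups (F1 physicochemical propensities, F4 sparse
   one-hot, F6 contact potentials, F7 quantum-topological descriptors),
   sequence-order descriptors (F11–F13 Moran/Geary/Moreau-Broto
   autocorrelation, F14 quasi-sequence-order, F15/F16 pseudo amino-acid
   composition), the F5 Smith-Waterman similarity profile against the
   training sequences, and predicted-structure descriptors (F17 relative
   accessible surface area, F18 secondary structure).
2. **Base predictors.** Each selected encoder's block trains its own
   random forest; the base output is the positive-class probability (the
   tree vote fraction). Probability averaging, rather than label voting,
   is used because AUC is the target metric and needs a continuous score.
3. **Ensemble and subset search.** The ensemble score is the unweighted
   mean of the selected base probabilities. A genetic algorithm searches
   the 2^18 subsets: a chromosome is the 18-bit membership indicator, and
   its fitness is the AUC of the subset's ensemble under internal
   stratified 5-fold cross-validation of the training set, computed on the
   pooled out-of-fold scores.

The assumptions are those of any sequence-only model: immunogenicity must
be predictable from the 9-mer's residues; the labels of the training
peptides are taken at face value; and the fixed peptide length of 9 is
baked into every encoder dimension (the code is written so other lengths
could be accommodated, but nothing else is validated).

### A note on the fitness computation

Averaging ensembles have a useful separability: each base predictor is
trained only on its own feature block, never on the subset context. The
internal-CV out-of-fold score of feature *j* for peptide *i* is therefore
identical whatever subset *j* sits in, and the package computes the
n × 18 matrix of per-feature out-of-fold scores once per training set
(`internal_cv_scores()`). A chromosome's fitness is then the AUC of the
row means of its selected columns — mathematically identical to retraining
the whole ensemble per chromosome (forest seeds are keyed to the feature's
identity to keep this exact), but roughly three orders of magnitude
cheaper. Fitness values are additionally memoized per bit pattern within a
run.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda` (F11–F13) | 7 | autocorrelation lag depth; admissible 1–8 for 9-mers (lags must stay below the sequence length) |
| `lambda` (F14) | 8 | number of sequence-order coupling terms per distance matrix |
| `lambda` (F15) | 8 | pseudo-composition sequence-order factors |
| `lambda` (F16) | 2 | amphiphilic correlation-factor pairs |
| `qso_w` | 0.1 | weight of coupling terms in quasi-sequence-order normalization |
| `pseaa_w` | 0.05 | weight of sequence-order factors in the pseudo-composition families |
| `ntree` | 500 | trees per base forest; `mtry` defaults to the square root of the block width, no depth cap |
| `pop_size` / `max_generations` | 100 / 100 | GA population and generation budget |
| `elite` | 2 | chromosomes copied unchanged each generation |
| `crossover_fraction` | 0.8 | share of non-elite offspring from uniform crossover (the rest are mutation-only children of rank-selected parents) |
| `mutation_rate` | 1/18 | per-bit flip probability |
| `stall_window` / `stall_tol` | 50 / 1e-6 | termination: stop when the best fitness improves less than the tolerance across the window |
| `internal_folds` | 5 | folds of the internal fitness CV |
| threshold | 0.5 | classification cutoff for SN/SP/ACC/MCC; ties classify positive |

The default lags are the best-performing values for each lag-parameterized
encoder family; the sequence-order weights are the conventional defaults
of the quasi-sequence-order and pseudo-composition literatures. GA
operator settings mirror common genetic-algorithm toolbox defaults
(elitist selection, 0.8 crossover fraction, one expected bit flip per
mutant) since the method family leaves them unspecified; all are
overridable through `ga_control()`.

## Data provenance of the bundled tables

* **Single-residue scales** come from the AAindex database copy shipped
  with the `seqinr` package, looked up by accession at run time
  (`aa_property_table()`); no values are duplicated into this package and
  no network access is needed. The F1 profile uses the 11 propensity
  scales established for this prediction task; the autocorrelation
  encoders use the 8 conventional descriptor-suite scales.
* **Grantham chemical distance** (first QSO matrix) is reconstructed from
  Grantham's own composition/polarity/volume properties (accessions
  GRAR740101/2/3) with his published weighting and the mean-100 scaling;
  the reconstruction reproduces the printed distances (e.g. Leu–Ile 5,
  Trp–Cys 215) to rounding.
* **Physicochemical distance** (second QSO matrix) is a documented
  in-package construction — Euclidean distance over standardized
  hydrophobicity (KYTJ820101), hydrophilicity (HOPT810101) and side-chain
  mass — in the style of the classical physicochemical distance matrix,
  whose exact published values are not freely available. It is symmetric,
  nonnegative and zero-diagonal, which is all the QSO formalism requires.
* **Contact-potential (F6) and quantum-topological (F7) lookup sets** are
  reconstructions: frozen lists of 40 and 21 complete AAindex scales
  (`AAPP_IDS`, `QTMS_IDS`, drawn evenly over the complete-entry accessions
  for diversity) reproduce the documented 360- and 189-dimensional
  shapes. Users holding the source descriptor tables can supply them as
  20×40 / 20×21 matrices via `encoder_context()`.
* **Structure annotations** (F17/F18) normally come from an external
  structure predictor. `sable_annotator()` parses a simple per-peptide
  report format (sequence, H/E/C string, nine RASA values); the bundled
  `surrogate_annotator()` is a deterministic per-letter stand-in (scaled
  tripeptide accessible-surface values; conformational-preference classes)
  that keeps the pipeline runnable closed-box and is clearly flagged as
  not being a structure prediction. Results using the surrogate measure
  what per-residue propensities alone can do — not what a real predictor
  would contribute.

## The synthetic generator

`synth_peptides()` draws two classes of 9-mers over the 20-letter
alphabet. Negatives come from a uniform background (configurable to
empirical frequencies); positives are perturbed by one of three
mechanisms: a multiplicative composition tilt `exp(effect)` on the
hydrophobic residue set LVIFM, a planted anchor-like motif (L at position
2 with probability `effect`), or a property shift weighting residues by
`exp(effect × z)` under standardized hydrophobicity. Effect size 0 makes
the classes exchangeable, giving an exact null; duplicates are resampled
so the no-duplicate invariant holds; generation is deterministic per seed
and restores the global RNG state.

Each mechanism is recoverable by a matched encoder family (composition →
F2/F8, motif → F4, property → F1/F13) and weakly or not at all by
mismatched ones, which is what gives the GA a planted truth to find. What
the generator does **not** emulate: real anchor-position biology, amino
acid background frequencies of the human proteome, label noise, or the
homology structure of curated epitope sets. Passing the synthetic suite
therefore demonstrates that the machinery is correct and sensitive, not
that the published benchmark numbers are reproduced; those require the
benchmark datasets themselves (see below).

## Numerical choices and degenerate inputs

* AUC is the Mann-Whitney rank statistic with midrank ties (ties count
  1/2), identical to the trapezoidal ROC area.
* Per-run AUC is computed on the pooled out-of-fold scores of that run;
  per-fold AUCs are retained for the feature-correlation analysis, which
  uses fold-level points for statistical stability.
* Zero-denominator threshold metrics (a fold without negatives, say)
  return `NA` with a warning and are excluded from averages.
* Moran and Geary autocorrelations of a zero-variance residue profile
  (homopolymers) would divide by zero; the affected entries are set to 0
  with a warning. No realistic peptide set contains homopolymer 9-mers.
* All-zero chromosomes (an empty ensemble has no defined fitness) are
  repaired by setting one uniformly random bit.
* Internal folds are stratified by class, so a degenerate internal fold
  cannot arise unless a class has fewer members than folds, which is
  rejected outright.
* Classification ties (score exactly at threshold) go positive, and the
  threshold is fixed at 0.5 for confusion-matrix metrics.
* Model files embed a format-version string and reload to bit-identical
  predictions.

## Open design points, resolved

* **F4 dimension.** The sparse profile is implemented as 9 × 20 = 180
  bits (one one-hot block per position), the operational reading of
  "merging the bit vectors for its amino acids"; a printed dimension of 20
  would collapse the profile to composition and lose positional
  information.
* **F1 layout.** The 99 dimensions are position-major (9 positions × 11
  scales); only the count is fixed by the method family, and the
  position-major layout keeps single-residue substitutions local.
* **λ bounds.** Lag-parameterized encoders accept 1–8 (a lag of 9 or more
  has no residue pairs in a 9-mer).
* **Internal fitness folds.** Five, per the method description; the
  alternative reading of ten appears only in a summary sentence and is
  noted as conflicting.
* **CLI.** A thin wrapper script (`inst/cli/epiga`) exposes the synth /
  encode / train / predict / ga-select / evaluate pipeline with plain
  flags; every option is a flag, so no separate configuration file format
  is maintained. Parallel fitness evaluation is unnecessary after the
  out-of-fold caching above, so no thread option exists.

## Demonstration problem sizes

The tests and the acceptance script exercise the pipeline at deliberately
compact sizes — a few hundred synthetic peptides, 40–150 trees per forest,
GA populations of 8–30 over 4–15 generations, 5-fold internal CV with 2–10
repetitions — chosen so the entire suite documents the method's behaviour
(signal recovery, null calibration, monotone elitism, exhaustive-search
agreement) in minutes. The defaults in the package itself
(`ga_control()`, `ntree = 500`, 20 × 10-fold evaluation) are the
full-protocol settings a benchmark study would run.

## Known limitations

* The IMMA2 and PAAQD benchmark datasets are not redistributable with the
  package; the two benchmark-reproduction acceptance tests report failure
  until the user supplies `inst/extdata/imma2.csv`. All other tests run
  closed-box.
* Surrogate structure annotations are per-letter propensities, not
  predictions; F17/F18 results with the surrogate understate (or at least
  misstate) what a real structure predictor contributes.
* The F6/F7 lookup sets are reconstructions with the documented shapes,
  not the source descriptor values, which are not freely available.
* Random-forest behaviour depends on the underlying implementation;
  seeded runs are exactly reproducible within this package but not across
  different forest libraries.
* The GA is a heuristic: it provably matches exhaustive search only on
  the small candidate spaces the tests enumerate (≤ 6 features); on the
  full 18-feature space it inherits the usual no-guarantee caveat.
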