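---
title: "Classifying lncRNAs and mRNAs from sequence, structure and putative protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lncRNAs and mRNAs from sequence, structure and putative protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts longer than 200 nt that do
not encode protein. Telling them apart from mRNAs using only the transcript
itself — no genome alignment, no homology search — is the core step in
annotating transcripts assembled from RNA-Seq, where most novel,
tissue-specific candidates have no cross-species support. `lncsieve`
implements an alignment-free classifier for this task: features are
extracted from the RNA primary sequence, from a predicted secondary
structure, and from the protein that each open reading frame (ORF) would
encode, and a gradient-boosted tree ensemble (XGBoost) separates the two
classes.

## Feature model

### Four ORF typologies

The longest conventional ORF of an annotated mRNA does not always coincide
with its annotated CDS, and tools that lean only on the longest start-stop
ORF misclassify exactly those mRNAs. We therefore segment each of the three
forward reading frames at in-frame stop codons (`TAA`, `TAG`, `TGA`) and
extract four ORF types:

* **T0** — first `ATG` of a stop-terminated segment through that stop (the
  conventional ORF; the stop codon is counted inside the ORF length);
* **T1** — first `ATG` of the trailing, stop-free segment through the last
  complete codon (start-anchored, no stop required);
* **T2** — a stop-terminated segment from its first codon (stop-anchored,
  no start required);
* **T3** — the longer of the best T1 and best T2.

Per type, the longest candidate over the three frames is the "max ORF";
ties are broken by lower frame, then smaller start, and a T1/T2 length tie
for T3 goes to T1 (the definition does not order them; the tie-break is a
documented constant). Only `ATG` counts as a start. Only forward frames
are scanned, since assembled transcripts are stranded. An absent ORF
contributes zeros to every derived feature, which keeps feature vectors
total.

From ORF geometry we take, per type, the max ORF length and its coverage
(length / transcript length), plus the mean length and mean coverage over
*all* T0 candidates.

### Sequence-intrinsic scores

* **GC content** `(N(G)+N(C))/L_t`.
* **Fickett TESTCODE score**: for each base, a position value
  (`max/(min+1)` over the three codon-phase counts) and a content value
  (base frequency) are looked up in the published 1982 probability tables
  and combined as a weighted sum of eight probabilities. The tables and
  weights are embedded verbatim in `R/fickett-tables.R`.
* **Relative codon bias (RCB)**: per codon `(x,y,z)`,
  `d = (f(xyz) − f1(x)f2(y)f3(z)) / (f1(x)f2(y)f3(z))` with positional
  base frequencies computed within the same ORF, combined as
  `(∏(1+d_i))^(1/L_codon) − 1` over codon instances. The exponent is read
  as `1/L_codon`: the product runs over the ORF's codons, and only that
  reading makes the statistic a geometric mean that is invariant to ORF
  length. Computed for each of the four max ORFs.
* **Hexamer usage score**: a class-conditional probability table over all
  `4^6 = 4096` hexamers is built from training data — CDS scanned with
  window 6, step 3 (one codon), so windows respect the reading frame;
  lncRNAs scanned with step 1, as they have none. A transcript is scored
  by the mean log-likelihood ratio `log(P_coding/P_noncoding)` of its
  hexamers, computed per frame at step 3 and maximised over the three
  frames; each max ORF is additionally scored in its own single frame.
  Step 3 is also used for transcript scoring (the table-building rule is
  mirrored; scoring windows are not specified independently). Zero counts
  use a bounded convention: a hexamer absent from both classes contributes
  0, absent from the coding class only −1, absent from the non-coding
  class only +1. This keeps single rare hexamers from dominating the mean.

### Secondary-structure features

Structures are dot-bracket strings with a minimum free energy (MFE,
kcal/mol), normally produced by RNAfold and read from its output format
(or a TSV); the package never recomputes thermodynamics. From a parsed
pair table we take the MFE, the paired ratio `N(paired)/L_t`, the GC
content of paired bases (0 when nothing pairs — the 0/0 case is defined
away), and a loop decomposition: each base pair closes a loop classified
by its directly enclosed helices — none = hairpin, one with unpaired bases
on both sides = interior, on one side = bulge, two or more = multibranch.
Stacked pairs close no loop and are not counted (the feature set has no
stack count), and the exterior region is not a loop. Counts and
per-nucleotide coverages of the four loop types are features.

The **SASS k-mer scores** (k = 1..5) join sequence and structure: a window
of width k over the two-row array of sequence and dot-bracket yields
tokens such as `"GG.("`; class-conditional token tables (dense sizes
`4^k·3^k` = 12, 144, 1728, 20736, 248832) are built over full transcripts,
and a transcript is scored by the mean mRNA/lncRNA log-likelihood ratio of
its tokens, with the same zero-count convention as the hexamer score.
Tables are stored sparsely (observed tokens only); the dense size is
exposed for validation. Tokens use the DNA alphabet internally; this is
purely presentational, U and T being interchangeable on input.

A transcript without a structure scores 0 on every SASS feature (with a
warning), which is what the structure-free mode relies on.

### Protein features

Each max ORF is translated (standard code, terminal stop dropped; the
segment rules guarantee no internal stop) and five physicochemical
quantities are computed on the peptide: isoelectric point (bisection on
the Henderson–Hasselbalch net charge over the free termini and D, E, C,
Y, H, K, R side chains, Bjellqvist pKa set, converged to |Q| < 1e-4 on
(0, 14)), molecular weight (average residue masses plus one water), grand
average of hydropathy (Kyte–Doolittle), aromaticity (F/W/Y fraction), and
the Guruprasad instability index (`10/L` times the sum of dipeptide
weights). Constant tables are embedded with their citations in
`R/protein-constants.R`. Degenerate peptides (length 0 or 1) score 0
rather than erroring, again keeping vectors total. Note one deliberate
deviation from a common reference implementation: our isoelectric point
bisects the full (0, 14) range, so strongly acidic peptides (e.g. poly-D)
report the true zero-charge pH rather than a clamped lower bound.

### The schema

The full schema has **57 features**: 21 sequence-intrinsic (GC, Fickett,
4 max ORF lengths, 4 coverages, average T0 length and coverage, the
transcript hexamer score, 4 ORF hexamer scores, 4 RCBs), 16
structure-derived (MFE, paired ratio, 4 loop counts, 4 loop coverages,
GC of paired bases, 5 SASS scores) and 20 protein features (5 × 4 ORF
types). The deployed default is the 28-feature subset selected by
recursive feature elimination on real training corpora — 14 SIFs, 6 SSFs
and 8 PFs, enumerated in `R/schema.R` — and the structure-free mode uses
those 28 minus the 6 SSFs. The schema lives in one file precisely so this
reconstruction can be revised in one place.

## Training pipeline

1. **Filtering.** Transcripts shorter than 200 nt or longer than 20,000 nt,
   or containing symbols outside `{A,C,G,T}`, are removed. Both bounds are
   inclusive (the corpus rule excludes strictly-below/above; whether the
   endpoints survive is our decision, recorded here).
2. **Tables.** The hexamer table needs each training mRNA's annotated CDS
   (not its longest ORF); SASS tables need structures on every record.
3. **Standardisation.** z-scores with *population* standard deviation
   (divide by n; the convention is unstated upstream, so it is pinned here
   and used identically at fit and apply time). Test data always uses the
   training statistics. Constant columns map to 0.
4. **Balancing.** SMOTE: synthetic minority rows are drawn on segments
   between a minority instance and one of its k = 5 nearest minority
   neighbours (`x + u(x_nn − x)`, `u ~ U(0,1)`) until the classes match.
   Originals are never modified. k is reduced with a warning when the
   minority class is tiny.
5. **Feature selection (optional).** RFECV: drop the single lowest
   gain-importance feature per round, record mean stratified 10-fold CV
   accuracy per subset size, keep the peak (ties to the smaller subset).
   Gain-based importance is used because that is the importance the
   boosted-tree model itself reports.
6. **Classifier.** XGBoost (`binary:logistic`), default 200 rounds, depth
   6, learning rate 0.1, single-threaded for determinism. A small
   documented grid (trees {100, 300, 500} × depth {4, 6, 8} × eta
   {0.05, 0.1, 0.3}) can be searched by 10-fold CV accuracy with
   `tune_classifier()`; tuning is opt-in because the defaults sit inside
   that grid and the full search costs 270 cross-validated fits.

Prediction applies the bundle's tables, scaler and classifier; the label
threshold is 0.5 with ties assigned to lncRNA, the positive class (the
class the tool exists to find). Evaluation implements Sn, Sp, Prec, Acc,
F-score and MCC from the confusion matrix, and ROC/AUC by threshold sweep
with trapezoid integration, which equals the rank-statistic (Mann–Whitney)
AUC — a property the test suite asserts to 1e-9.

## The synthetic data generator

Real training corpora (GENCODE lncRNAs, RefSeq mRNAs with CDS) require
downloads and hours of RNAfold; the package instead ships a generator that
emulates the two signals the classifier actually exploits:

* mRNA-like records embed a start-to-stop ORF covering at least half the
  transcript (default `orf_fraction = 0.5`), with synonymous-codon usage
  skewed 8-fold towards one preferred codon per amino acid
  (`codon_bias = 8`) — a synthetic usage pattern, deliberately not any
  organism's table. Flank GC is tuned so the class mean hits
  `gc_mrna = 0.52`.
* lncRNA-like records are i.i.d. sequence at `gc_lncrna = 0.45` with stop
  codons salted into every frame so no open run exceeds 50 codons.
* Lengths are uniform on 200–600 nt for both classes — long enough that
  every stage (folding, SASS tables, ORF typology) is exercised, short
  enough that a 4,000-transcript study folds and trains in minutes.
* Structures come from `fallback_fold()`, a deterministic Nussinov-style
  base-pair maximisation DP (canonical pairs plus GU wobble, minimum
  hairpin gap 3, traceback prefers pairing then the leftmost partner,
  pseudo-energy = −pairs). Its output is explicitly **not** an RNAfold
  substitute scientifically — it maximises pair count, not free energy —
  but it produces well-formed, sequence-dependent dot-brackets, which is
  all the structural feature code needs for testing. Bundles record their
  structure source so a fallback-trained model is never mistaken for an
  RNAfold-trained one.

GC defaults reflect the direction seen in real data (coding transcripts
GC-richer than non-coding); the 0.07 gap keeps GC informative without
making it the only signal. What the generator does *not* emulate: splice
structure and UTR composition, expression levels, sequence conservation,
the heavy length skew of real corpora, and real thermodynamic structure.
Passing the signal-recovery tests therefore shows the pipeline is wired
correctly and can recover a planted class difference; it says nothing
quantitative about accuracy on real transcriptomes, which depends on real
corpora and real RNAfold structures.

## Numerical and design choices

* Zero-count log-ratio convention (above) bounds each token's contribution
  to [−1, 1] instead of ±∞.
* RCB uses `exp(mean(log(f/f_indep))) − 1`; every observed codon has
  positive positional frequencies, so the logs are always finite.
* The isoelectric-point bisection runs at most 100 halvings of (0, 14),
  far past the 1e-4 charge tolerance.
* Degenerate inputs (empty peptides, structures with no pairs, ORF-free
  transcripts, constant feature columns) all map to 0 by decision, never
  to NA or an error, so downstream matrices stay total.
* Determinism: all randomness (generator, SMOTE, fold assignment, XGBoost)
  is seeded, XGBoost runs single-threaded, and multi-threaded feature
  extraction only parallelises over records with an ordered merge — the
  test suite asserts bit-identical matrices and byte-identical re-trained
  bundles.
* The fallback folder guards at 2,000 nt: the DP is cubic and longer
  transcripts belong in RNAfold anyway.

## Problem sizes used by the checks

The signal-recovery study trains on a 70/30 split of 2,000 + 2,000
generated transcripts and asserts held-out accuracy ≥ 0.95 and AUC ≥ 0.98
with structures, and accuracy ≥ 0.90 without them. Oracle-equivalence
suites run the ORF engine against exhaustive enumeration on 500 random
60–600 nt sequences and the loop decomposer against an independent
recursive reference on 500 folded structures. These sizes are the
package's chosen study conditions and are fixed in the tests and the
acceptance script.

## Known limitations

* The 28-feature default subset is carried over from feature selection on
  real human corpora; RFECV on synthetic data may select differently,
  which is expected and not an error.
* Only nested (pseudoknot-free) structures are supported — a limitation
  inherited from dot-bracket notation itself.
* Non-canonical starts (CUG/GUG) are out of scope; T1-type ORFs partially
  compensate by not requiring a stop.
* The classifier is trained for human-like transcript statistics when used
  with real corpora; distant species need retraining, which
  `train_model()`/the CLI support directly.
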