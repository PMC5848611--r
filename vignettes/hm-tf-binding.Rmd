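---
title: "Quantifying histone-modification signatures at TF binding sites"
author: "hmtf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone-modification signatures at TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

A transcription factor's core motif occurs far more often in a genome than
the factor actually binds. Even restricting attention to accessible
chromatin, most exact copies of the motif are unbound. `hmtf` implements a
matched-control design for asking what distinguishes the bound copies: for
each in vivo binding site (BS, defined by a ChIP-seq peak containing the
motif), a non-BS is selected that (i) carries an *exactly identical* core
motif sequence, (ii) lies in accessible chromatin at a distinct locus, and
(iii) has chromatin accessibility as close as possible to the BS's own.
Under this pairing, core-motif sequence and accessibility are controlled by
construction, and whatever still separates the classes must live in the
flanking sequence, the local DNA shape, the histone-modification (HM)
environment, or nucleosome occupancy. Those are exactly the feature
families the package quantifies.

Two complementary analyses are built on the matched pairs:

1. **Differential HM statistics.** For each of the 10 histone marks carried
   by default (`hm_marks()`), the per-site mean coverage over the motif
   ± 1 kb window (RPM units) is compared between BSs and their matched
   non-BSs with *both* one-sided Wilcoxon signed-rank tests. Each one-sided
   p-value is Bonferroni-corrected by the family size (2 directions × 10
   marks = 20 by default) and capped at one, and the signed summary is

   Δ[−log₁₀(q)] = (−log₁₀ q_greater) − (−log₁₀ q_less),

   positive when HM levels around BSs significantly exceed those around
   non-BSs. This definition makes Δ exactly antisymmetric under swapping
   the class labels, which the tests assert to machine precision. The exact
   arithmetic combining the two one-sided q-values into one signed number
   admits alternatives; this difference-of-logs form is recorded in the
   `run_study()` manifest so downstream consumers know which was used.

2. **Classification and deconvolution.** Sites become feature vectors:
   one-hot flanking sequence (A→1000, T→0100, G→0010, C→0001), four DNA
   shape features (MGW, ProT, Roll, HelT) per flank position from a sliding
   pentamer table, one window-average RPM value per HM mark, and optionally
   mean nucleosome occupancy. An L2-regularized multiple linear regression
   (ridge on the 0/1 labels — deliberately *linear* regression used as a
   classifier, scores being the linear predictor) separates the classes,
   with the penalty λ selected by embedded stratified 10-fold
   cross-validation maximizing the area under the precision–recall curve
   (AUPRC). Comparing feature combinations (sequence+shape;
   sequence+shape+HM; HM-only; sequence+shape+nucleosome) yields percent
   AUPRC gains; the 5% (HM) / 15% (sequence+shape) thresholds classify each
   TF's binding mode as `HM_specific`, `seq_shape_specific`, `other`, or
   `both` (the both-above-threshold quadrant has no canonical name; a
   fourth label is emitted rather than forcing one of three).
   Leave-one-feature-out (LOFO) refits without one group at a time —
   the whole sequence block, one shape feature, or one HM mark — and
   records the percent AUPRC decrease (15 groups with the default marks).

## Model evaluation choices

How the AUPRC relates to training deserves care. `evaluate_variant()`
defaults to **nested cross-validation**: 10 outer stratified folds, λ
re-selected by the embedded CV inside each outer training fold, AUPRC
computed on the pooled held-out scores. This avoids the optimism of
in-sample evaluation while keeping λ selection strictly inside training
data; `scheme = "insample"` is available for comparison. AUPRC itself is
average precision with tied scores treated as one threshold block, so it is
invariant under any strictly monotone transform of the scores.

The ridge solver standardizes continuous features (shape, HM, nucleosome —
their units range from Ångströms through degrees to RPM, so a shared λ is
only meaningful on a common scale) with training-fold statistics, leaves
the binary sequence indicators unscaled, and never penalizes the intercept.
The λ path is computed from the symmetric eigendecomposition of the Gram
matrix, with near-null directions dropped (the pseudo-inverse convention)
so λ = 0 reproduces ordinary least squares on full-rank problems — a fact
the tests check against `lm()`. The λ grid is 25 log-spaced values in
[1e−4, 1e4].

## Feature-encoding conventions

* Flank lengths for sequence/shape are 5, 10, or 15 bp per side; with
  5-bp flanks the sequence+shape block is exactly 80 columns
  (8 features × 2 × 5 positions), the model's minimum feature count and
  the reason the dataset filter requires at least 132 sites.
* Shape values are attributed **per flank position for all four
  features**, the step parameters (Roll, HelT) being assigned to the
  centered pentamer's position. This per-position attribution is the only
  reading consistent with the 80-column minimum; it is also recorded in
  the manifest.
* Shape prediction needs 2 bp of context on each side of a payload
  position. The innermost flank positions take the first two core-motif
  bases as context; the outermost take genomic context. Flanks are encoded
  independently — no pentamer window spans from one flank across the core
  to the other.
* All sequence work happens on the motif strand: minus-strand sites are
  reverse-complemented, their flanks swapped, and their signal windows
  mirrored. Reverse-complementing the whole genome while flipping strands
  leaves every feature vector unchanged (tested).
* Sites whose flanks contain `N` or fall off a chromosome end are dropped;
  in a paired collection the partner is dropped too, preserving matching.
* The bundled pentamer table (`toy_shape_table()`) is **synthetic**:
  deterministic trigonometric functions of base identity mapped into
  physically plausible ranges, reverse-complement symmetric for MGW, ProT,
  HelT and antisymmetric for Roll. It carries no experimental content and
  exists so the pipeline and its tests are self-contained; real tables load
  via `read_shape_table()` (missing pentamers completed from the reverse
  complement, Roll negated).

## Background matching choices

Exact-motif candidates come from scanning accessible regions on both
strands; within one region only the first occurrence in scan order is kept
(leftmost position, plus strand on a palindromic tie). Matching is greedy
without replacement in BS coordinate order, each BS taking the unused
candidate minimizing the absolute difference in mean accessibility over the
site ± 1 kb window (ties to the smallest coordinate). A globally optimal
assignment is not attempted: the goal is distribution matching, greedy is
deterministic and O(n·m), and on synthetic studies the two-sample KS
distance between class accessibility distributions comes out far below the
0.1 the tests require. Matching without replacement keeps every non-BS
locus distinct. The imbalanced variant (`bootstrap_imbalanced()`) resamples
non-BSs with replacement to five times the BS count.

## The synthetic-study generator

`generate_study()` emulates the statistical structure the analysis assumes,
not read-level realism. One random genome (GC 0.41 by default) receives,
per TF, `n_bs` motif instances sampled from the TF's PFM (strand
Bernoulli(½)), each wrapped in a 200-bp peak whose summit is the motif
center, plus `n_decoys` exact copies of sampled BS cores at distinct loci
without peaks. When `n_decoys ≥ n_bs` every BS is guaranteed at least one
exact-copy decoy, so truth-based pairing is total. Signal tracks are
exponential background noise plus one Gaussian bump (SD 150 bp, peak
amplitude 10 background units, lognormal site-to-site jitter) per site:
accessibility bumps are identically distributed in both classes (making
accessibility matching possible and honest), each HM bump is scaled by
2^δₘ at BSs only, and the nucleosome bump is scaled by 2^−depletion at
BSs (default depletion 1). A `flank_bias` knob rewrites BS flanks with a
GC-enriched composition so flank-sequence-driven TFs can be simulated;
`generate_family_panel()` builds TF families sharing HM-effect vectors and,
via `sharing_fraction`, placing that fraction of a TF's BSs within 300 bp
of a same-family partner's BS, giving recoverable co-occupancy structure.

Sites are placed on a shuffled slot grid (genome length / total sites per
slot, jittered), which guarantees non-overlapping cores and raises an
explicit capacity error when the genome cannot host the requested sites at
the spacing the window analysis needs. Far tails of neighboring windows may
still overlap; that contamination is class-symmetric noise. The default PFM
is 10 bp with dominant-base probability ≈ 0.95 — sharp enough that an
implanted instance is, up to rare chance windows, the best PWM hit in its
own peak and scores above the default scan threshold. With soft motifs
that guarantee degrades gracefully (a weak core can legitimately lose to a
chance near-consensus window elsewhere in the peak); the scanner is doing
its job in that case, and the tests allow the corresponding small slack.

What the generator does *not* emulate — read-count discreteness,
fragment-length structure, nucleosome phasing, GC bias, copy-number
variation, real motif co-occurrence grammar — bounds what green tests mean:
they certify the statistical machinery (calibration under the null, sign
and importance recovery under known effects, matching quality,
co-occupancy recovery), not performance on real ChIP-seq data.

## Scanning and dataset filters

`scan_best_site()` takes the maximum log-odds hit over both strands and all
offsets; under a fixed background the maximal score is the minimal match
p-value, so the best-scoring hit implements the lowest-p rule for multiply
matching peaks (ties: lowest offset, then plus strand). The default score
threshold is the log-odds value corresponding to a per-site match
probability of 1e−4 under a uniform background (`default_score_threshold()`),
the usual motif-scanner default. A TF dataset is rejected when fewer than
132 sites survive — keeping the sample size above the 80-feature minimum
model — or when the mode of motif-center − peak-center offsets falls
outside ±25 bp (the summit-coincidence filter; no numeric tolerance is
canonical, so it is a documented, configurable knob). Rejections are
values, not errors, so `run_study()` records them and continues with the
remaining TFs.

## Statistics details and degenerate inputs

* Wilcoxon signed-rank: exact p for ≤ 25 nonzero differences, normal
  approximation with continuity correction above; zero differences are
  dropped (standard convention). All-identical input returns q = 1 both
  ways and Δ = 0.
* The label-shuffle control permutes labels within pairs (each pair
  independently with probability ½), preserving the paired design under
  the null.
* The paired t-test for cross-condition group comparisons returns p = 0 or
  1 for a noise-free constant shift (t = ±∞) and errors only when all
  differences are zero, where t is genuinely undefined.
* The nucleosome/accessibility shift test is the unpaired two-sided
  Wilcoxon rank-sum on per-site window means.
* Co-occupancy: BSs of A overlapping a BS of B (≥ 1 bp) are discarded
  first; B's peaks are extended ±300 bp; the proximal percentage is
  relative to A's site count before discarding, making the measure
  asymmetric in the pair, as intended. The ΔH3K4me3 "difference ratio"
  denominator is not canonical; the symmetric pair mean is the default
  (scale-free, symmetric), with `max` and `first` selectable.
* log base 10 throughout the Δ statistic.

## Problem sizes used by the tests

The test suite runs the full design at desk scale, chosen once: recovery
studies use 200 BSs (+2 log₂ units on one mark, or flank bias 0.8) on 1-Mb
genomes over 20 seeds; null calibration uses 100 TFs at 150 pairs with
500-bp HM windows (within the supported 10–2000 bp range); co-occupancy
panels use 3 families × 3 TFs at 140 BSs each. At these sizes the expected
effects are unambiguous (the spiked-mark Δ is ≈ 30, two orders above the
shuffle null's envelope) while a full `R CMD check`-style run stays
comfortably within an ordinary desktop budget.

## Known limitations

* Ridge-on-labels is the deliberate model choice (matching the linear
  "regression as classifier" design); no logistic or nonlinear variants.
* Bonferroni is the only multiplicity correction offered; the family is
  per TF (2 × number of marks) and configurable, but FDR alternatives are
  out of scope.
* Per-position differential testing of HM profiles is not implemented;
  profiles are descriptive (`meta_profile()`), inference is on window
  means.
* bigWig input requires `rtracklayer`; bedGraph is the canonical on-disk
  track format otherwise, and BAM is not read at all — per-base coverage
  is expected as input.
* The matching is one-to-one within a TF; cross-TF shared backgrounds and
  matching on further covariates (GC content, binding energy) are not
  supported.
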