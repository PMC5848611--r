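# hmtf

Quantifies what distinguishes a transcription factor's (TF's) in vivo
binding sites (BSs) from unbound, accessibility-matched exact copies of the
same core motif (non-BSs): flanking DNA sequence, DNA shape,
histone-modification (HM) patterns, and nucleosome occupancy.

A TF's core motif occurs orders of magnitude more often than the TF binds.
Chromatin accessibility explains much of the difference — but not all of
it: even among accessible exact-motif copies, most are unbound. `hmtf`
implements a matched-control design for the remainder. For each BS (a
ChIP-seq peak aligned against a position frequency matrix, best hit per
peak), a non-BS is selected with a string-identical core motif, at a
distinct accessible locus, with the closest mean chromatin accessibility in
the motif ± 1 kb window. On these pairs the package computes:

* **Differential HM statistics** — per mark, both one-sided Wilcoxon
  signed-rank tests on the paired per-site window averages (RPM),
  Bonferroni-corrected, summarized as the signed statistic
  `Δ[−log₁₀(q)] = (−log₁₀ q_greater) − (−log₁₀ q_less)` (positive = higher
  HM around BSs), plus per-base meta-profiles and a label-shuffle null.
* **L2-regularized MLR classification** — ridge regression on 0/1 labels
  over one-hot flanking sequence (A=1000, T=0100, G=0010, C=0001), four
  pentamer-derived DNA shape features (MGW, ProT, Roll, HelT) per flank
  position, per-mark HM averages, and nucleosome occupancy; λ chosen by
  embedded stratified 10-fold cross-validation maximizing AUPRC, evaluated
  by nested cross-validation.
* **Binding-mode deconvolution** — percent AUPRC gains of the HM-augmented
  model over sequence+shape and HM-only baselines, thresholded at 5% / 15%
  to call each TF `HM_specific`, `seq_shape_specific`, `other`, or `both`;
  leave-one-feature-out importance over 15 feature groups.
* **Co-occupancy and nucleosome analyses** — percentages of one TF's BSs
  within 300 bp-extended peaks of another, intra- vs inter-family rank-sum
  tests, cross-condition BS overlap partitioning, and two-sided shift tests
  on per-site nucleosome occupancy.

A fully seeded synthetic-study generator (`generate_study()`,
`generate_family_panel()`) creates genomes with implanted motifs, peaks,
matched accessibility bumps, per-mark HM effect sizes (log2 units), and
family-shared placement — with ground truth — so the whole pipeline is
testable end to end.

## Worked example

```r
library(hmtf)

# a synthetic study: one TF whose H3K4me3 level around true BSs is
# 2^2 = 4-fold the level around unbound exact-motif copies
eff <- setNames(rep(0, 10), hm_marks())
eff["H3K4me3"] <- 2
cfg <- synth_config(synth_tf("TF1", n_bs = 200, n_decoys = 250,
                             hm_effect = eff),
                    genome_length = 1e6, seed = 1)
res <- run_study(cfg)
print(res)
#> hmtf study: 1 TF(s) analyzed, 0 rejected
#>   TF1 [famA]: 198 sites, AUPRC ss=0.500 ss+hm=0.900, mode HM_specific

subset(res$tf$TF1$delta, mark == "H3K4me3")
#>      mark    delta   q_greater q_less
#> 4 H3K4me3 29.24076 5.74434e-30      1
```

Reading: the pipeline aligned 198 of the 200 peaks to their implanted
motifs (the best-hit rule and scan threshold drop the rare weak instance),
matched each BS to an exact-motif non-BS of closest accessibility, and
found H3K4me3 significantly elevated around BSs (corrected
q ≈ 5.7 × 10⁻³⁰, so Δ[−log₁₀ q] ≈ +29.2, positive = BS-enriched; all other
marks sit at Δ = 0). Sequence+shape features alone perform at chance
(AUPRC 0.50 — core motifs are identical by design and flanks carry no
signal here), while adding the 10 HM averages lifts AUPRC to 0.90, a
relative gain of ~80%, so the TF is called `HM_specific` (HM gain above
the 5% threshold, sequence+shape gain below 15%). Per-stage functions (`align_binding_sites()`,
`select_matched_nonbs()`, `build_feature_matrix()`, `delta_log_q_all()`,
`evaluate_variant()`, `leave_one_feature_out()`, `cooccupancy_pairs()`)
expose every intermediate.

See `vignettes/hm-tf-binding.Rmd` for the model, its assumptions, and the
design decisions.

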