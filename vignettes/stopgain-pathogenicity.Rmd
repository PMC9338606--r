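---
title: "Predicting stopgain pathogenicity at clinical sensitivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting stopgain pathogenicity at clinical sensitivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

A stopgain substitution replaces a sense codon with TAG, TAA or TGA and
truncates the protein. Whether that truncation causes disease depends on an
interaction of mechanisms: how much of the protein is lost, whether the
mRNA is destroyed by nonsense-mediated decay (NMD), whether the ribosome
reads through the new stop or reinitiates at a downstream ATG, how
intolerant the gene is to loss of function, and — crucially — whether one
intact allele suffices (zygosity). In the clinic the classifier's decision
rule must retain at least 95% of pathogenic variants; performance is
therefore judged inside the high-sensitivity region of the ROC curve, not
over the whole curve.

## The model

`stopgainr` scores a variant with a gradient-boosted tree (GBT) ensemble
over a fixed 32-feature schema (see `feature_schema()`); `featurize()`
documents each feature. Three modelling commitments matter:

1. **Variant identity is the 5-tuple** `(chrom, pos, ref, alt, zygosity)`.
   The same locus may legitimately appear twice with opposite labels —
   benign as a heterozygote, pathogenic as a homozygote — and both records
   are kept, which lets the trees learn a decision boundary in the
   zygosity direction. Clinical databases usually omit zygosity; for those
   records it is imputed: if the training set contains a *benign
   heterozygous* allele at the same locus (healthy carriers exist, so the
   allele must act recessively), the variant is predicted homozygous,
   otherwise heterozygous. Hemizygous counts as homozygous throughout.
2. **Transcript averaging.** Any feature that can vary across transcripts
   is computed per transcript and averaged — unweighted — over the
   transcripts in which the variant actually creates a stop codon.
   Isoforms in which the same genomic substitution is synonymous or
   missense do not contribute: including them would leave stopgain-specific
   features (the new stop codon, the junction distance) undefined. Only
   coding-complete transcripts (CDS a positive multiple of 3) enter the
   average; malformed annotations are loaded, flagged, and excluded.
3. **Missingness is information.** No junction (single-exon transcript),
   no downstream ATG, no RVIS entry, no expected-LoF denominator — each is
   encoded as a native missing value, and the tree learner routes missing
   values through whichever child of each split maximises the training
   gain. Nothing is median-imputed and missing is never coded as 0.

### Training-derived features and leakage

Several features are functions of the *training* labels: the
observed/expected ratio (benign training stopgains along the gene divided
by the expected loss-of-function count), the monoclass-pathogenic
transcript/exon flags (at least one pathogenic and zero benign training
variants), and the zygosity-imputation index. These are collected in a
`training_context` built exclusively from the training split; a dedicated
test asserts that rebuilding the context with test variants changes the
features, i.e. accidental leakage would be visible, and the dataset
assembler additionally routes every variant known to external tools into
the training split (4-tuple matching, since external lists lack zygosity).

### Learning algorithm

The GBT is implemented in the package (no boosting library exists in the
target environment): logistic loss, depth-limited trees grown on quantile
histograms (255 bins), second-order (Newton) leaf updates with L2
regularisation, and split thresholds placed halfway between adjacent cut
points so held-out values falling in an empty margin are routed sensibly.
Training uses no randomness at all — no subsampling, no tie-breaking by
RNG — so a fixed fold assignment yields byte-identical models.

Hyperparameters are chosen by stratified fivefold cross-validation
maximising the pooled out-of-fold **hsr-AUROC** rather than the overall
AUROC; this is what "tuned for the clinical regime" means operationally.
The default grid is small (tree depth 2–3, learning rate 0.1, 150 trees,
minimum child weight 5), sized for desk-scale cohorts; the published
method does not disclose its settings, so these defaults are the
package's own. Optional switches reproduce two robustness experiments:
benign subsampling (`rebalance`) and greedy backward feature elimination
(`select_features`, off by default — with 32 engineered features and CV
noise, elimination rarely helps at this scale).

### Calibration and normalisation

The clinical threshold θ is the largest score such that at least 95% of
pathogenic *calibration* variants score ≥ θ, computed on pooled
out-of-fold training predictions. The paper-scale alternative — calibrate
on the test set — would contaminate the only untouched partition, so the
test split is never used for calibration here; applying θ back to its
calibration scores achieves the target sensitivity by construction, and
the held-out sensitivity is then an honest estimate. Raw scores are
mapped to percentiles against a reference distribution by the mid-rank
rule `100·(#ref < s + ½·#ref = s)/n`, which is monotone and invariant
under joint strictly increasing transforms.

### Metrics

With the ROC written as FPR(t) along TPR = t,

* `hsr_auroc = ∫_{0.95}^{1} (1 − FPR(t)) dt / 0.05`,

with linear interpolation where the curve crosses the floor. The
normalisation by `1 − floor` makes a perfect classifier score 1 and the
chance diagonal score 0.025; the source method inherits its hsr
normalisation from earlier work without printing the formula, so this
definition is documented as the package's interpretation (with floor → 0
it reduces exactly to the AUROC, which a test asserts to 1e-9). TNR@95 is
`1 − FPR` at the least-stringent threshold reaching 95% sensitivity.
Equal scores are grouped into single threshold steps (diagonal ROC
segments); AUPRC uses step-wise interpolation.

## The synthetic world

`simulate_cohort()` builds a self-contained cohort: a toy genome of
multi-exon genes (default 80 genes, 2–10 exons of 90–240 bp, introns
80–400 bp, strands and chromosomes mixed, ~10% chrX), extra isoforms that
skip one codon-aligned internal exon (so exon-skipping and frame logic are
exercised without frameshifts), per-base conservation drawn around a
gene-level mean that tracks a latent intolerance parameter, resource
tables consistent with that parameter (RVIS decreasing in intolerance,
expected-LoF tracking CDS length — intolerance must surface through the
*dearth of observed benign variants*, not through the denominator), and
5000 labelled stopgain variants sampled from the enumerated set of
genuinely stop-creating substitutions.

Labels are drawn from `Bernoulli(plogis(b0 + Σ wᵢ mᵢ))` where the
mechanisms m are the variant's relative truncation position, NMD flag,
stop-codon identity (TGA protective), reinitiation opportunity (5′-proximal
variant with a nearby downstream ATG), gene intolerance, zygosity within
recessive genes, and the realised downstream phyloP mean. This makes
end-to-end signal recovery a fair test — the features measure exactly the
mechanisms that generated the labels — without claiming population-genetic
realism: there is no coalescent, no linkage, no ascertainment. A green
end-to-end test therefore establishes that the pipeline recovers planted
mechanism signal at realistic separability; it does not establish clinical
accuracy on real cohorts.

**Default effect weights.** The defaults (`w_location = w_nmd =
w_zygosity = w_conservation = 2`, `w_stop_codon = w_reinit = 1.5`,
`w_oe = 3`, 2% label noise, 30% class prior) were calibrated once so that
the *Bayes ceiling* of the synthetic world — metrics computed with the
true generative logit as the score — matches the separability reported on
real clinical stopgain data (AUROC ≈ 0.93, TNR@95 ≈ 0.7), and then frozen.
A first draft with weaker weights produced a world markedly harder than
the real phenomenon (ceiling AUROC ≈ 0.87), which would have made the
synthetic benchmark misleadingly pessimistic. Remaining knobs with
stated-world defaults: 25% of pathogenic records have their zygosity
masked (mirroring databases that omit it), 5% of recessive homozygous
pathogenic variants get a benign heterozygous twin at the same locus, 4%
of variants receive a common (≥1%) allele frequency to exercise the rare
filter, and 10% of loci go on the external-overlap list to exercise
forced-to-train routing.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF positions convert at
  the boundary. On the minus strand, CDS offsets count from the 3′-most
  genomic base and codons are read on the coding strand.
* The "downstream" conservation region starts at the first base of the
  variant's codon (the truncated portion begins at the premature stop), so
  upstream and downstream lengths always sum to the CDS length.
* The downstream-ATG scan accepts any reading frame (reinitiation does not
  preserve frame); an in-frame-only mode exists.
* The NMD rule is strict: flag 1 iff the stop is > 50 coding bases
  upstream of the last exon–exon junction; single-coding-exon transcripts
  have a missing distance and flag 0.
* The chromosome class is encoded as two dummies (is_chrX, is_chrY),
  equivalent to a ternary code for trees.
* Odds ratios apply the Haldane–Anscombe 0.5 correction when any cell is
  zero; CV ties between grid configurations break deterministically to
  the first configuration; `calibrate_threshold(target = 0)` returns the
  top score (everything may be called benign).
* Allele-frequency filtering is strict (`AF < 0.01`) and treats a missing
  frequency as rare — a variant absent from reference cohorts is rare by
  definition.
* The `oe` denominator prefers the per-transcript expected-LoF table and
  falls back to the per-gene table; whether the source method used gene or
  transcript expectations is not stated, so both tables are accepted.

## Open choices made here

* The train/test split fraction is not published; the default is 0.9,
  approximating the reported set-size ratio, and is a parameter.
* RVIS enters as both raw score and percentile when available.
* Non-coding isoforms never count toward transcript overlap or averaging.
* The permutation-importance recovery check (doubling the conservation
  weight promotes downstream phyloP) is asserted on the seed-averaged
  rank: correlated conservation and intolerance features share permutation
  credit, so per-seed ranks are noisy by construction.
* Acceptance-scale experiments run at the stated n = 5000 over three
  seeds; the byte-determinism check runs the identical full pipeline at
  n = 2000 with a one-configuration grid to stay inside the suite's time
  budget (determinism does not depend on n).

## Known limitations

Only single-nucleotide stopgains are modelled — no frameshifts, no splice
disruption, no multi-nucleotide substitutions; UTR and intronic positions
map to "no consequence". The synthetic world shares its mechanism list
with the feature library, so it cannot detect a *missing* biological
mechanism, only broken plumbing or lost signal. Real-data performance
claims require real cohorts (HGMD/ClinVar-grade labels, gnomAD
frequencies), which this package deliberately does not depend on.
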