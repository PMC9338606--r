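# stopgainr

Pathogenicity prediction for stopgain (nonsense) variants, calibrated for
the high-sensitivity regime of clinical variant triage.

## The problem

A stopgain substitution converts a sense codon into one of the three stop
codons (TAG, TAA, TGA) and truncates translation. Stopgains are among the
largest classes of disease-causing variants, yet any sequenced individual
also carries a dozen or more rare *benign* stopgains — variants that hit
loss-of-function-tolerant genes, truncate little of the protein, escape
nonsense-mediated decay (NMD), are read through, or are rescued by
translation reinitiation at a downstream start codon. A clinically useful
classifier must therefore keep essentially every pathogenic variant
(sensitivity ≥ 95%) while discarding as many benign ones as possible: the
quantity that matters is not the overall AUROC but the area of the ROC
curve restricted to the region TPR ≥ 0.95 (the **hsr-AUROC**) and the
true-negative rate at the 95%-sensitivity threshold (**TNR@95**).

## What the package does

* **Consequence calling and features** — transcript-aware stopgain calling
  from VCF against GenePred/GTF + FASTA annotations, and a fixed, versioned
  32-feature schema: variant zygosity (observed, or imputed for clinical
  databases that omit it: a variant whose locus has benign heterozygous
  carriers in the training set is predicted homozygous); gene/exon
  essentiality (a stopgain-specific observed/expected ratio, RVIS, OMIM
  dominant/recessive flags, monoclass-pathogenic transcript and exon flags,
  exon skippability across isoforms); truncation location (distances and
  relative position in CDS and exon); NMD (signed distance to the last
  exon–exon junction, the strict >50 bp rule, percent of transcripts
  predicted to degrade); the identity of the new stop codon (read-through
  propensity ranks TGA > TAG > TAA); distance to the next downstream ATG
  (reinitiation); and regional phyloP/phastCons means upstream, downstream
  and across the overlapped exon. Transcript-varying features are averaged
  over the transcripts in which the variant is a stopgain; missing values
  stay missing.
* **Dataset curation** — 5-tuple variant identity `(chrom, pos, ref, alt,
  zygosity)` so the same locus may be benign as a heterozygote and
  pathogenic as a homozygote; allele-frequency filter (strictly < 1%,
  missing treated as rare); exclusion lists routed into the training split
  to prevent leakage against external tools; seeded variant-level split
  (gene-held-out mode available).
* **Classifier** — a deterministic, in-package gradient-boosted tree
  learner (histogram splits, second-order leaf updates, native
  missing-direction routing), tuned by stratified fivefold CV that
  maximises the out-of-fold hsr-AUROC, with the decision threshold
  calibrated on pooled out-of-fold predictions to guarantee the sensitivity
  target, and percentile normalisation of raw scores against a reference
  set.
* **Evaluation** — AUROC, AUPRC, hsr-AUROC, TNR@95, plus the feature
  diagnostics used to verify class separation: odds ratios with 95% Woolf
  intervals, one-sided Welch *t*-tests, Pearson chi-squared with Bonferroni
  correction.
* **Synthetic cohorts** — a generator that emits a toy genome (multi-exon,
  multi-isoform coding genes on autosomes/X/Y), conservation tracks,
  resource tables and labelled stopgain variants whose labels are drawn
  from a logistic model over the same mechanisms the features measure, so
  the entire pipeline trains and evaluates offline at desk scale.

## Worked example

Everything below runs from R (a shell entry point with the same
subcommands is installed at `inst/scripts/stopgainr.R`):

```r
library(stopgainr)

dir <- tempfile("cohort")
cmd_simulate(dir, seed = 1)                      # 5000-variant toy cohort
cmd_build_dataset(dir, file.path(dir, "dataset"), seed = 1)
cmd_train(dir, file.path(dir, "dataset"), file.path(dir, "model"), seed = 1)
cmd_evaluate(dir, file.path(dir, "model"), file.path(dir, "dataset"),
             file.path(dir, "metrics"))
cmd_score(dir, file.path(dir, "model"), file.path(dir, "variants.vcf"),
          file.path(dir, "scores"))
```

which prints, for this seed:

```
simulate: wrote 10 artifact(s) to /tmp/.../cohort
build-dataset: 201 common variant(s) removed, 4812 retained
train: best CV hsr_auroc = 0.4294, theta = 0.2311
evaluate: AUROC 0.9116, AUPRC 0.9152, hsr-AUROC 0.4117, TNR@95% 0.6488
score: imputing zygosity for 703 variant(s)
```

Reading the numbers: 201 variants exceeded the 1% allele-frequency cutoff
and were removed; cross-validation selected the configuration whose pooled
out-of-fold hsr-AUROC was 0.429 and calibrated the 95%-sensitivity
threshold to 0.231; on the untouched test split the model reaches AUROC
0.912 and, at ≥95% sensitivity, correctly discards 64.9% of benign
stopgains. `scores.tsv` then contains, per variant, the raw score, its
percentile against the model's reference distribution, and the
benign/pathogenic call at the calibrated threshold; the 703 imputations are
the variants whose VCF records carry no genotype.

## Acceptance script

`scripts/acceptance.R` re-runs that complete pipeline from scratch —
simulate, curate, train with CV, evaluate, score — under a given seed and
writes the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

```
R/                 gene models, conservation, curation, features, GBT,
                   classifier, evaluation, simulator, pipeline commands
src/               histogram kernel for the tree learner (Rcpp)
inst/scripts/      command-line entry point
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette (model, assumptions, design choices)
scripts/           acceptance.R
```
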