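---
title: "Foldability from sort-seq: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foldability from sort-seq: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(foldscan)
```

## The problem

Disulfide-constrained peptides (DCPs) and de novo hyperstable constrained
peptides (HCPs) are 20–50 residue scaffolds whose folds are pinned by two
or three disulfide bonds. They make excellent starting points for
combinatorial display libraries, but randomizing the wrong positions
destroys the scaffold's ability to fold at all: much of such a library is
then dead weight, and the hits that do come out may be unfoldable in
vitro. `foldscan` implements a sequence-based route to deciding which
positions of a scaffold are safe to randomize:

1. A **shotgun alanine scan** library (each scanned position wild-type or
   alanine, encoded by degenerate codons) is displayed on yeast and
   sorted once for successful display, which the secretory quality
   control machinery makes a proxy for folding.
2. Pre- and post-sort populations are sequenced with UMIs;
   design-matched, UMI-deduplicated counts give per-position residue
   frequencies before (`F_orig`) and after (`F_exp`) sorting.
3. The **Enrichment Score** per residue and position is
   `ES = (F_exp - F_orig) / (1 - F_orig)` when `F_exp > F_orig` and
   `ES = (F_exp - F_orig) / F_orig` otherwise, a signed, bounded
   ([-1, 1]) measure of how much selection favored that residue.
4. Per-sequence post/pre count ratios are percentile-labeled
   (High/Mid/Low foldability), and a small self-attention classifier is
   trained on the labeled sequences of all scaffolds but one.
5. **Integrated Gradients** attribution of the held-out scaffold's
   High-foldability probability yields a predicted per-residue ES, and
   thresholding at the scaffold-wide average yields the
   **non-touchable** map: positions that a new library must not
   randomize.
6. Library designs follow from the map: NNK randomization of amenable
   positions ("positive" design), or of non-touchable positions
   ("negative" control design), with cysteines always fixed.

Because raw sort-seq data cannot ship with a package, `foldscan` includes
a first-class simulator that generates the whole study — scaffolds,
libraries, selection, UMI-tagged reads — from planted ground truth, so
every stage is testable end to end.

## Statistical conventions

* **ES edge cases.** A residue absent from both samples is the
  indeterminate 0/0 case of the second branch; it scores 0, encoding "no
  information". `F_orig = 0` with `F_exp > 0` falls in the first branch
  and is finite. Positions a design never randomizes (cysteines, fixed
  positions, wild-type alanines) have no measurable ES: they are
  reported as `NA`, treated as non-touchable by convention, and excluded
  from accuracy metrics.
* **Per-position summary.** Each position is summarized by the ES of its
  *wild-type* residue: in an alanine scan, enrichment of the retained
  wild-type residue is the natural per-position measure of dependence on
  that residue. The full position-by-residue matrix is also kept for
  heat maps.
* **Criticality cutoff.** `call_critical()` defaults to `ES >= 0.4`,
  reflecting that well-designed hyperstable scaffolds show mostly
  positive ES with a median near 0.4, so residues at or above it are
  the clearly indispensable ones.
* **Non-touchable threshold.** The scaffold-wide arithmetic **mean** of
  the per-position scores is the default; the **median** is available
  (`threshold = "median"`) since both conventions appear in practice.
  Scores at the threshold are non-touchable (`>=`).
* **Percentiles.** Labeling uses linear interpolation between order
  statistics (R's `quantile(type = 7)`) with *strict* inequalities:
  ratios above the 95th percentile are High, below the 5th Low,
  boundary ties go to Mid. With 100 distinct ratios this yields exactly
  5 High and 5 Low.
* **Mid balancing.** The Mid class is uniformly subsampled, without
  replacement, to `min(|High|, |Low|)`; High and Low are never touched.
  The subsample is a pure function of its seed.
* **Ratios.** Sequences absent from the post-sort table get ratio 0;
  sequences absent from the pre-sort table have an undefined ratio and
  are excluded by default (a 0.5-UMI pseudocount mode retains them).
  The default normalization denominator is the matched UMI total, which
  makes frequencies a proper distribution; a total-read-volume mode is
  available and the choice is recorded in the table metadata, and both
  tables entering a ratio must use the same convention.
* **Adjusted F1.** Three classes collapse to binary labels with Mid
  treated leniently (a Mid truth scores correct regardless of the
  prediction; only Low-called-High and High-called-Low are errors), and
  F1 is computed with Mid-High as the positive class; zero-division
  returns 0 with a warning. The always-High baseline has the closed
  form `2m / (2m + l)` for `l` Low and `m` other truths — 0.8 on
  balanced classes — and a useful model must beat it. The unadjusted
  macro F1 is reported alongside.
* **Similarity.** Pairwise scaffold similarity is global
  Needleman–Wunsch alignment under BLOSUM62 (gap open −10, extend −1);
  similarity is the percentage of alignment columns whose residue pair
  scores strictly positive, with gap columns in the denominator. The
  percentage depends on this convention, which is therefore fixed,
  configurable, and stated here.

## The classifier

The published recipe fine-tunes a large pretrained protein language
model; pretrained weights are deliberately out of scope here, so the
default backbone is a compact encoder trained from scratch behind the
same interface (tokenize → logits), and a pretrained checkpoint can be
plugged in through that interface instead.

* **Architecture** (`training_config()`): residue + position embeddings
  (width 64), two residual self-attention blocks (4 heads, GELU MLP of
  width 128), mean pooling, a dense GELU layer (width 64) and a 3-logit
  projection. At this depth the blocks are stable without normalization
  layers, which keeps the explicit backward pass (needed for
  attribution) simple. GELU uses the standard sigmoid approximation
  `x * sigmoid(1.702 x)`.
* **Presets.** `"published"` is the published fine-tuning recipe: AdamW,
  learning rate 1e-5, weight decay 0.01, dropout 0.1, cross-entropy, 10
  epochs, all layers trainable. `"desk"` (default) keeps weight decay
  and dropout but uses learning rate 1e-3 over 30 epochs — the step
  size a small randomly-initialized encoder needs; preset choice is
  recorded in the model object.
* **Determinism.** Class order is fixed (Low, Mid, High) so attribution
  targets index 3 unambiguously. Initialization, shuffling and dropout
  all flow from `config$seed`; equal seeds give bitwise-identical
  models on one platform. Prediction uses no randomness and is
  batch-order equivariant.

## Integrated Gradients

Attribution of the High-foldability output follows the straight-line
path integral from a baseline to the input in embedding space.

* **Baseline**: the null/mask token's embedding at every position — a
  sequence in a neutral state.
* **Target**: the softmax probability of the High class; a logit
  target is provided because probabilities saturate near 0/1 and
  flatten gradients.
* **Integration**: midpoint Riemann rule, 64 steps by default
  (trapezoid optional). The completeness axiom — attributions summing
  to `F(x) − F(baseline)` — is verified in the test suite within 1% at
  256 steps, and the linear-model closed form is matched exactly.
* **Which sequence is attributed** for a scaffold's predicted ES is
  genuinely underdetermined; the default attributes the parent scaffold
  sequence, and `mode = "top_high"` averages attributions over the k
  library variants with the highest predicted High probability.
  Predicted ES inherits the *ranking* of measured ES, not its scale, so
  only thresholding/ranking is contractual.
* **Evaluation discipline**: predicted maps are always produced by a
  model trained without the target scaffold (leave-one-scaffold-out),
  and accuracy is compared against the all-non-touchable baseline,
  whose accuracy equals the prevalence of measured non-touchable flags.
  Validation is on the held-out scaffold's balanced dataset by default
  (the same construction as training); full-set evaluation is a flag.

## What the simulator emulates — and what it does not

`make_benchmark_suite()` generates nine scaffolds (lengths 28–47, four
or six non-adjacent cysteines) with five planted folding-critical
positions each, a full-coverage shotgun alanine-scan design, and one
round of display selection at 50,000 reads per sample over 500 unique
variants — sizes chosen to mirror a small MiSeq-scale screen while
keeping a full leave-one-scaffold-out experiment runnable on a laptop
CPU in minutes.

The generative model is **additive-logistic**: a variant's display
probability is `logistic(beta0 + sum of beta over retained critical
residues)` with `beta = 3` per critical position and `beta0` centered
just below half-retention, so fully retained variants display almost
surely while fully mutated ones still display at a small, sequenceable
rate (one FACS round enriches; it does not annihilate — and the
de-enriched tail must remain quantifiable for ratio labeling to have a
Low class). Post-sort counts are multinomial with weights proportional
to display probability; pre-sort counts are multinomial-uniform.

Critical positions carry strongly hydrophobic core residues
(L/I/V/F/W/M) against a polar/small background. This encodes the
hydrophobic-core determinant of small disulfide-stabilized folds:
burying core residues is what selection rewards, and — crucially for
cross-scaffold generalization — criticality is then legible from the
sequence itself, which is what lets a classifier trained on eight
scaffolds transfer to a ninth it has never seen.

Features of real screens deliberately *not* emulated: epistasis between
positions, PCR amplification bias, FACS gating noise, UMI sequencing
errors (deduplication is exact-match), partially hydrophobic surface
positions, multi-round selection, and scaffolds whose folding is
insensitive to sequence (the "permissive" scaffolds that are hard for
the real method too). Passing the recovery benchmark therefore shows
the pipeline's statistics, learning and attribution are implemented
correctly and can recover a planted, sequence-legible signal — it does
not certify performance on real screens, where the signal is weaker
and less transferable.

An analytic reference accompanies the simulator: under uniform library
sampling the expected wild-type ES at each position follows in closed
form from averaging the logistic weight over the binomial count of
other retained critical residues (`expected_wt_es()`), and the test
suite checks law-of-large-numbers convergence of measured ES to it at
depth 10^6 within 0.02.

## Read processing choices

Merged, sense-strand reads are assumed (paired-end merging is a solved
upstream step). The anchor adjacent to the UMI is required at its fixed
offset — a chance anchor-like k-mer inside the random UMI must not
shift the reading frame — while the far anchor is located by its
outermost occurrence. Reads with `N` in the UMI or coding region, with
a missing anchor, an off-frame coding length, an internal stop codon,
or a translation outside the library design are rejected and tallied by
reason; matched plus rejected always equals total. UMI errors are not
corrected (no error model is assumed), so a sequencing error in a UMI
would create a spurious molecule — at the simulator's error-free
default, read emission followed by counting reproduces count tables
exactly, which the tests exploit as a pipeline-inversion check.
Reverse translation during emission uses the design's codons where
given and otherwise the alphabetically first codon per amino acid, for
determinism.

## Problem sizes and runtime

The default benchmark (9 scaffolds × 500 variants × 50,000 reads, desk
preset, 64-step attribution) was sized so the complete
leave-one-scaffold-out experiment — nine training runs plus attribution
and evaluation — completes in minutes on a single CPU; the encoder's
forward/backward passes are written against BLAS-backed matrix
primitives for that reason. `scripts/acceptance.R` re-runs exactly this
experiment from scratch at a caller-supplied seed.

## Known limitations

* The compact from-scratch encoder is not a pretrained protein language
  model; on real data its sample efficiency would be far lower, and the
  package's interface accepts a pretrained backbone for that reason.
* ES values carry no uncertainty quantification (point estimates only,
  matching how the statistic is used); depth and library size control
  their noise.
* The non-touchable threshold (mean vs median) changes maps for skewed
  profiles; both are implemented, the mean is the default, and the
  choice is recorded in every map.
* `adjusted F1` is by construction lenient to Mid predictions (an
  always-Mid predictor scores 1.0); it should always be read next to
  the always-High baseline and the macro F1, as the evaluation
  functions encourage.
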