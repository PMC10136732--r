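---
title: "Methods: pathway-structured classification of tumor-educated platelet RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-structured classification of tumor-educated platelet RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

Blood platelets take up tumor-derived RNA and alter their own splicing
program in cancer patients, which makes their RNA-seq profile a usable
liquid-biopsy analyte. `teptools` implements a complete
cancer-versus-non-cancer classification workflow over splice-variant
count matrices: count quality control and annotation-based filtering,
size-factor normalization with a variance-stabilizing transform (VST),
KEGG-style pathway feature preselection, a per-sample pathway-grid image
encoding, two class-weighted classifiers (gradient boosting and a compact
convolutional network), and an evaluation harness for the four questions
a clinically minded reader asks of such a classifier: does it work on an
internal split, does the image layout matter, does pathway preselection
help, and does it survive transfer to an unseen collection site.

Because the clinical cohorts are external data, every quantitative claim
in this package is made on synthetic data from a generator whose job is
to emulate the *statistical structure* of such a study — not platelet
biology. All numbers reported by the tests, the analysis scripts and
`scripts/acceptance.R` are computed at run time by this code.

## The synthetic study

`simulate_counts()` draws counts for variant $i$ in sample $j$ as
negative binomial with mean

$$\mu_{ij} = s_j \, q_i \, f_i^{\,z_j} \, b_{\mathrm{site}(j),i},
\qquad \mathrm{Var} = \mu + \alpha\mu^2,$$

with $s_j$ a log-normal library-size factor, $q_i$ a log-normal base
expression level, $f_i$ the planted fold change ($1$ for non-informative
variants; direction up/down drawn with equal probability, since platelet
markers are reported in both directions), $z_j$ the binary cancer label,
and $b$ a per-site multiplicative effect on a configurable variant
subset. One seed drives every draw through an explicit RNG scope, so a
config plus seed reproduces the study bit-for-bit.

Default conditions (chosen once, as study conditions, not tuning knobs):
800 samples at 500 cancer / 300 control (the ~63/37 imbalance of the
motivating cohorts), 2,000 splice variants with 100 informative at
2–3-fold, dispersion $\alpha = 0.2$ (a typical bulk RNA-seq value),
4 collection sites, and a 40-pathway database cycling over the eight
KEGG-style groups. The library-size log-mean is 0.25 so that the median
library lands near 150,000 reads: the fixed 100,000-read QC threshold
then excludes a small fraction (~8%) of samples, exercising QC without
decimating the cohort, as in a study where most samples pass quality
control. Base expression uses fixed shape constants (log-normal,
meanlog $\log 20$, sdlog 1.5), giving the heavy-tailed per-gene
abundance profile of real libraries.

What the generator deliberately does *not* emulate: isoform structure
within genes, correlated co-expression modules, batch effects beyond
multiplicative per-site factors, and label noise. Passing tests
therefore show that the pipeline recovers structure it is designed for;
they do not certify performance on clinical data.

The annotation generator plants two complications the preprocessing must
handle: a configurable fraction of gene names carried by two variant ids
(usually at different annotation levels, sometimes at the same level),
and a fraction of variants with status other than `known`. The pathway
generator guarantees a configurable fraction of informative genes
pathway membership and keeps the remainder out of every pathway, and
injects unmapped member ids, so preselection benefit and unmapped-ID
removal are both testable.

## Preprocessing

The fixed order is QC → known-status filter → level dedup → size
factors → dispersion → VST.

* **QC**: samples with *less than* 100,000 total reads are excluded; a
  sample at exactly the threshold is retained.
* **Known-status filter**: variants absent from the annotation or with
  status other than `known` are dropped.
* **Dedup**: when several variant ids share a gene name, the lowest
  annotation level wins (Level 1 over Level 2). The annotation convention
  only covers that case, so among equal levels we keep the id with the
  larger total count, breaking exact ties by the lexicographically
  smaller id — deterministic and data-driven. Surviving features are
  relabeled to gene names, which is what pathway membership is keyed on.
* **Size factors**: the standard median-of-ratios estimator. If no
  variant is positive in every sample, the reference falls back to
  variants with ≥ 90% nonzero samples (geometric mean of positive
  counts, medians over positive ratios), an explicit poscounts-style
  rule; if even that fails the error says so.
* **Dispersion**: a pooled method-of-moments estimate — the median over
  variants of $\max(0, (v_i - m_i)/m_i^2)$ on normalized counts, floored
  at $10^{-4}$. A full per-gene dispersion trend is out of scope; the
  VST below only needs a common $\alpha$ of the right magnitude, and the
  estimator recovers $\alpha = 0.2$ within a few percent at study scale.
* **VST**: the closed-form common-dispersion transform
  $v(q) = \bigl(2\,\mathrm{asinh}\sqrt{\alpha q} - \ln 4\alpha\bigr)/\ln 2$
  applied to $q = k_{ij}/s_j$. It is monotone, equals
  $-\log_2 4\alpha$ at $q = 0$, and converges to $\log_2 q$ for large
  $q$ (at $\alpha = 1$: $v(3) = 1.800$, $v(100) = 6.6511$ vs
  $\log_2 100 = 6.644$). A practical note on testing the "stabilizing"
  claim: at large $\alpha$ the dispersion term dominates the log-scale
  variance at *all* means, so plain $\log_2(k+1)$ is already nearly
  stabilizing there. The regime that separates the two transforms is
  small $\alpha$ with low means, where the Poisson $1/\mu$ term varies
  strongly; the variance-ratio tests therefore run at $\alpha = 0.01$
  over means 5–10,000, where the VST holds the per-stratum variance
  ratio near 1 and the raw log exceeds 10.

## Pathway grid and preselection

`preselect_features()` returns the union of pathway member genes that
are actually measured, in first-occurrence order; unmapped pathway
members are dropped and out-of-pathway genes are excluded.
`build_images()` lays one pathway per row (rows grouped by the eight
groups in their canonical order, file order within a group), one member
gene per cell, in GMT member order. Three conventions the image encoding
needs but no annotation standard supplies are fixed explicitly:

* rows are right-padded with 0 to the maximum pathway width;
* pixels are min-max scaled to $[0,1]$ with constants computed on the
  training partition only and reused (clipped) for validation/test —
  scaling on all samples would leak test information;
* a gene in $m$ pathways appears in $m$ cells with equal value.

The row/column permutation experiment is the guard that none of these
layout choices is load-bearing: `permute_images()` applies one
seed-determined permutation to every sample, and
`images_to_features()` produces the order-canonicalized flat matrix
(deduplicated genes, lexicographic column order) that makes any
flat-feature model provably invariant to layout.

## Classifiers

**Gradient boosting** (`train_boosting()`) wraps xgboost behind the
package's model contract. The random search draws `n_settings`
hyperparameter settings — learning rate log-uniform on $[0.01, 0.3]$,
depth uniform on $\{2..8\}$, estimator cap uniform on $[50, 1000]$,
input-feature dropout (column subsampling) uniform on $[0.1, 1]$ —
fits each `repeats_per_setting` times with distinct seeds and early
stopping (patience 15 on validation log-loss), and keeps the setting
with the best mean validation AUC, ties going to fewer estimators and
then smaller depth. Defaults are 150 settings × 3 repeats; the tests and
scripts use smaller searches (stated per script) because the selected
model saturates on the synthetic studies long before that. Sample
weights implement inverse-frequency class weighting,
$w_c = n/(2 n_c)$, making plain accuracy under the weights equal to
balanced accuracy. Feature importance is total gain, with never-used
features appended at zero; gain is fixed as the importance flavor and
noted as an assumption.

**Compact CNN** (`train_implatelet()`): two 3×3 convolutions with four
filters each, then dense layers of 256/64/16/1 units with dropout 0.3
after the first two — ten layers, eight of them hidden (two
convolutional, four dense, two dropout); hidden activations are
rectified-linear, the output sigmoid, the loss class-weighted binary
cross-entropy, and the optimizer adadelta ($\rho = 0.95$,
$\epsilon = 10^{-6}$). No R deep-learning framework is a package
dependency: the network is implemented directly in vectorized R (im2col
convolution with explicit backpropagation), which keeps it deterministic
under one seed in single-threaded mode and trivially installable. The
model returned is the epoch checkpoint with the best validation loss;
the epoch budget defaults to 100, and the dense widths/dropout rate are
the package's own choices within that layer plan. Images must
be at least 5×5 for two valid 3×3 convolutions.

## Evaluation harness

* `stratified_split()`: `round(0.3 n)` test samples with per-class
  largest-remainder rounding, remainder dealt round-robin into five
  stratified folds.
* `location_split()`: assignment purely by collection site; unlisted
  sites are excluded and reported.
* `balanced_accuracy()`: mean per-class recall, threshold fixed at 0.5
  (natural after class-weighted training).
* `roc_auc()`: the rank (Mann–Whitney) formulation, ties counting one
  half; the tests hold it exactly equal to an $O(n^2)$ pair-counting
  oracle. ROC points come from a threshold sweep over unique scores.
* Experiment runners assert train/test id-set disjointness before every
  fit (scaling constants, importance rankings and search selection are
  train-partition-only); repeats use distinct seeds and report
  per-repeat values plus the arithmetic mean. The importance ranking
  that seeds the feature sweep is fit on the training partition — not
  on the entire dataset — to keep the sweep leakage-free.

The four experiments mirror the study design: internal comparison
(5-fold CV + held-out test, three repeats), permutation of image rows
and columns with the boosting control, preselection versus all
features, hospital transfer (internal validation versus unseen-site
test, no adaptation), pathway-group ablation, and the
importance-limited feature sweep (best test AUC per feature budget over
a fresh random search).

The transfer harness is validated in both directions. With site effects
independent of the label, internal and external AUC agree closely. The
confounded scenario plants a deliberately adversarial study: weak
biology (1.1–1.2-fold on 20 variants), strong site effects (log-SD 1.0
on 30% of variants), and a 90/10 label-site association, with
cancer-enriched and control-enriched sites on both sides of the
train/test boundary. The classifier then partly keys on site signatures
that do not transfer, and the external AUC drops far below the internal
one — the detectable failure mode the harness exists to expose.

## Problem sizes and numerical choices

The tests and the acceptance script run the full method at reduced
scale, stated here as the package's own choices: the default 800 × 2,000
study for the end-to-end and null checks; 250–400-sample studies with
400–1,200 variants for the preselection, permutation, transfer and
sweep experiments; random searches of 2–10 settings; CNN budgets of
10–25 epochs (the planted signal saturates the validation loss well
before that). Degenerate inputs are handled explicitly: empty QC result,
all-duplicate genes, constant feature matrices (warned, not fatal),
constant scores (AUC 0.5 with a warning), images smaller than 5×5, and
single-class label vectors all raise or warn with informative messages.

## Known limitations

* The generator's independence across variants understates the
  correlation structure of real transcriptomes, which inflates
  classifier performance relative to clinical data; the synthetic AUCs
  near 1.0 validate machinery, not clinical utility.
* The common-dispersion VST ignores the per-gene dispersion trend a
  full RNA-seq pipeline would fit.
* The CNN is intentionally small; at clinical scale (hundreds of
  pathway rows) a compiled backend would be the natural replacement
  behind the same model contract.
* Residual-style image classifiers and MixUp-style augmentation are out
  of scope; the model contract (`predict_proba()` over a fitted object)
  is the extension point.
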