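---
title: "Predicting pseudouridine sites with chemical-property features and random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pseudouridine sites with chemical-property features and random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pseudouridine (Ψ) is the most abundant internal RNA modification: an
isomer of uridine produced enzymatically by rotating the base and
re-bonding it through a carbon–carbon glycosidic linkage. It occurs in
rRNA, tRNA, mRNA and small nuclear RNAs, and affects RNA structure,
translation and immune recognition. Experimental Ψ mapping is costly, so
sequence-based classifiers are used to triage candidate sites.

psiforest frames the task as binary classification of *U-centered
fragments*: odd-length windows with a uridine at the exact center,
labeled by whether that uridine is pseudouridylated. The shipped species
profiles use 21-nucleotide windows for *H. sapiens* and *M. musculus*
and 31-nucleotide windows for *S. cerevisiae*. (One section of the
original report lists the window lengths in a different species order;
we follow the Methods-level assignment H=21, M=21, S=31, and
`species_profile()` documents the discrepancy.)

## Encoders

**NCP (default).** Each nucleotide maps to three binary chemical flags —
ring class (purine/pyrimidine), functional group (amino/keto), hydrogen
bonding (weak/strong) — giving A=(1,1,1), C=(0,1,0), G=(1,0,0),
U=(0,0,1). A window of length $n$ becomes a $3n$-vector: 63 features for
21-mers, 93 for 31-mers. Every pair of codes differs in exactly two
flags, so no nucleotide shares more than one property class with
another; the code is injective while staying three-dimensional per
position. Feature numbering is 0-based: position $i$ occupies features
$3i..3i{+}2$, so the constant central U of a 21-mer occupies features
30–32.

**CKSNAP.** For gaps $g = 0..k_{\max}$ and each ordered pair $(x,y)$,
the count of positions carrying $x$ and, $g+1$ steps later, $y$, divided
by the number of such position pairs ($n-g-1$). Default $k_{\max}=5$
(96 features), the common convention; the original comparison did not
state its setting.

**PseKNC (Type I).** Normalized $k$-tuple frequencies damped by
$w$-weighted sequence-order factors $\theta_j$, each $\theta_j$ the mean
squared distance between standardized property vectors of dinucleotides
$j$ apart; the vector has $4^k+\lambda$ entries and sums to one.
Defaults $k=2$, $\lambda=2$, $w=0.5$, again the original settings being
unstated. The shipped property table holds six A-form duplex base-step
parameters (shift, slide, rise, tilt, roll, twist) for the 16 RNA
dinucleotides, standardized per property to zero mean and unit variance
(population SD over the 16 values); it obeys reverse-complement
symmetry. Because the original comparison's PseKNC variant and property
set are unknown, its printed comparison numbers are documented but never
asserted.

**Ambiguity.** `N` (used to pad edge windows) encodes as (0,0,0) under
NCP and is excluded from CKSNAP/PseKNC counts — no chemistry is invented
for an unknown base.

## The classifier

A random forest of 200 trees. Two hyper-parameters are tuned by
exhaustive grid search: maximum tree depth over $\{2,...,6\}$ and the
per-split feature fraction over $20\%..80\%$ in 5% steps — 65
combinations, each evaluated on the *same* stratified 5-fold split
(a paired comparison). Choices the original description left open, fixed
here as package defaults:

* **Stratification and seeding.** Folds are stratified (per-fold class
  counts within one of balance) under a single configurable seed; the
  benchmark is balanced and reproducibility requires a declared stream.
* **Feature fraction → count.** `round(fraction * n_features)`, minimum 1.
* **Selection score.** Mean fold accuracy (the quantity the original
  heat-maps display); MCC and pooled-over-folds aggregation are
  available via `grid_spec(criterion=, aggregation=)` because the
  original text does not say whether its cross-validation numbers are
  fold means or pooled.
* **Tie-breaking.** Highest score, then smaller depth, then smaller
  fraction — prefer the simpler model.
* **Calling threshold.** A fragment's score is the fraction of trees
  voting positive; calls use threshold 0.5. The original never discusses
  thresholds.

Impurity importances are normalized to sum to one. A feature that is
constant across the data can never improve a split, so its importance is
exactly zero for any seed — in particular the three NCP features of the
always-U central position. This is asserted, not assumed, in the tests.

## Evaluation metrics

From confusion counts: SN = TP/(TP+FN), SP = TN/(TN+FP),
ACC = (TP+TN)/total, and MCC, the Matthews correlation coefficient. On
balanced classes ACC = (SN+SP)/2 exactly, which makes printed
per-class rates and accuracies mutually checkable. Degenerate cases are
explicit: an empty class yields `NA` with a warning (never a silent 0),
and an MCC denominator factor of zero yields 0 by the standard
convention. Note two distinct symmetries, which are easy to conflate:
exchanging the class *roles* (truth and calls together) swaps SN↔SP and
leaves ACC and MCC unchanged, while flipping only the predicted calls
negates MCC.

## Per-position enrichment (two-sample logo)

For each (position, nucleotide) cell, each fragment contributes a 0/1
indicator; the positive and negative sets are compared with a two-sided
pooled-variance Student t-test on the indicators (the two-sample-logo
convention; Welch via `var_equal = FALSE`). A cell with $p < \alpha$
(default 0.05) is *enriched* or *depleted* by the sign of the frequency
difference. No multiple-testing correction is applied, matching the
conventional per-cell usage; this is deliberately liberal and the TSV
output carries the raw p-values so users can correct as they see fit.
Cells with zero variance in both groups — the central U above all — get
`NA` and no call.

## The synthetic generator

`simulate_dataset()` draws each position independently from a background
distribution (uniform by default, the null the enrichment test assumes),
forces the central U in both classes, and overrides chosen positions of
the positive class with planted nucleotide probabilities. It emulates
the *structure* of the real benchmark — balanced classes, fixed odd
window, central U, position-specific enrichment such as the G-enrichment
the real *H. sapiens* and *S. cerevisiae* sets show — but not its
dependence structure: real fragments have correlated neighboring
positions, compositional bias, and near-duplicate windows from homologous
transcripts. Passing the recovery tests therefore demonstrates that the
pipeline detects positional signal of realistic strength, not that it
attains any particular accuracy on real data.

The package's strong-signal reference profile (`strong_signal_spec()`)
plants G with probability 0.9 at four off-center positions (0-based 4,
8, 12, 16) of a 21-mer over a uniform background, 400+400 fragments. A
single biased position was rejected at design time: with one position
the Bayes-optimal accuracy is $(0.9 + 0.75)/2 = 0.825$, below the 0.9
bar the recovery check uses; with four independent biased positions the
likelihood-ratio computation gives Bayes accuracy ≈ 0.948, leaving a
tuned forest headroom to clear 0.9.

## Problem sizes used by the shipped checks

Unit tests run on 9- and 21-mers with tens to hundreds of fragments;
the recovery checks use the 400+400 strong-signal profile under the
full default 65-combination grid, a 25-replicate null calibration of
the enrichment test (100+100 fragments each), and one end-to-end run on
a benchmark-shaped 495+495 set with a reduced grid. These sizes give
stable statistics while keeping a full test run in the low minutes on
one CPU.

## Reproducing the published numbers

The real benchmark (training sets of 628/944/990 fragments and two
100+100 independent test sets) is third-party supplementary data and is
not redistributed here. If you supply it as FASTA pairs,
`run_cv()`/`run_train()`/`run_evaluate()` reproduce the published
protocol end-to-end; expect small deviations from the printed
cross-validation and test values, since random-forest results depend on
seeds the original work did not state. What *is* checked exactly, with
no external data: the encoder dimensionalities (63/93), and that the
printed independent-test per-class rates, combined with the 100+100
test composition, reproduce the printed ACC (74.00 / 75.00) and MCC
(0.48 / 0.50) under the metric formulas.

## Known limitations

* Per-position independence in the generator (above).
* No probability calibration; the vote fraction is not a calibrated
  posterior.
* No AUROC/PR evaluation, no feature selection, no alternative learners
  — all deliberately outside the method's scope.
* The logo plot is a diagnostic rendering (letters sized by frequency
  difference), not a typographically exact sequence logo.
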