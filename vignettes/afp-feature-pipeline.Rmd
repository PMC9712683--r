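---
title: "Profile-based feature encoding and evaluation for antifreeze-protein prediction"
author: "afpkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based feature encoding and evaluation for antifreeze-protein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpkit)
```

## The problem and the model

Antifreeze proteins (AFPs) depress the freezing point of body fluids by
binding ice crystals. They are a hard classification target: AFP
families share little sequence or structural similarity, so no single
descriptor separates them from background proteins. The approach
implemented here fuses complementary views of a protein:

* **composition** of the primary sequence, at two granularities — five
  physicochemical residue groups (GAAC) and 400 ordered residue pairs
  (DPC);
* **evolutionary conservation**, read from a PSI-BLAST
  position-specific scoring matrix (PSSM) — an $L \times 20$ matrix
  $A_{m,n}$ of log-odds scores for residue type $n$ at position $m$;
* **local profile structure**, by cutting the PSSM into three
  contiguous row blocks and summarizing each block separately, so that
  N-terminal, core and C-terminal conservation patterns are not washed
  out by a global average;
* **residue-order information** within those blocks, via lagged
  autocovariance and squared-difference (pseudo) statistics.

A tree-ensemble classifier is then trained on the fused feature vector,
after recursive feature elimination prunes the uninformative majority.

## The four encoders

**GAAC.** $F(G_k) = n(G_k)/n$ for the groups G1 = AGLIMV (aliphatic),
G2 = DE (negative), G3 = FWY (aromatic), G4 = HRK (positive),
G5 = CNPQST (uncharged). Five features summing to 1; defined for any
non-empty validated sequence.

**DPC.** Frequency of each ordered dipeptide among the $L-1$ adjacent
pairs. We take the denominator to be $L-1$ — the number of dipeptides
that actually occur — so the 400 values always sum to 1 and the encoder
is compositional; a constant denominator of 400 would make the vector
scale with sequence length instead.

**Normalization.** PSSM log-odds are unbounded integers, so both
profile encoders first squash every entry with the logistic sigmoid
$f(t) = 1/(1+e^{-t})$, mapping scores into $(0,1)$ while preserving
order. Only the log-odds block of the PSI-BLAST file is used; the
weighted-percentage block is already bounded and carries redundant
information. Normalizing twice is an error by construction, because a
second squashing would silently destroy the scale.

**Partitioning.** Both profile descriptors split the $L$ rows into
three contiguous blocks of sizes
$\lfloor L/3 \rfloor, \lfloor L/3 \rfloor, L - 2\lfloor L/3 \rfloor$:
the remainder rows go to the third (C-terminal) block, consistent with
the floor operator being attached to the first two. Internally blocks
are 0-based half-open ranges; user-facing output is 1-based to match
PSSM file position indices.

**PseTS-PSSM.** Each slice contributes its 20 column means — the
composition of the conservation profile in that region — for
$3 \times 20 = 60$ features. The pseudo extension adds, per slice and
per configured rank $r$, the 20 factors
$\bar R^{r}_n = \frac{1}{S-r}\sum_{m=1}^{S-r}\left(R_{m,n} - R_{m+r,n}\right)^2$
capturing how quickly conservation changes along the slice. The default
configuration is means-only: that is what yields the canonical printed
dimensionality of 60, while the rank factors are exposed as an opt-in
(`encoder_config(pse_mode = "means+corr", pse_ranks = 1:2)` gives 180
features). The sources describing this descriptor family are ambiguous
about whether the published 60 dimensions include correlation factors;
we follow the printed count and keep both readings available.

**Sg-PSSM-ACT.** Each segment contributes, per lag $\ell$, the 20
per-column autocovariances
$ACT_n^{\ell} = \frac{1}{S-\ell}\sum_{m}\left(A_{m,n}-\mu_n\right)\left(A_{m+\ell,n}-\mu_n\right)$
where $\mu_n$ is the **segment's own** column mean — the mean is
subscripted by segment, never global — and pairs never straddle segment
boundaries. The denominator is the number of summed pairs
(segment length minus lag) for every segment, including the longer
third one. The default lag set is $\{1\}$ (60 features), again
following the canonical dimensionality; `act_lags = c(1, 2)` yields
120. Autocovariance is invariant under reversing a segment (a property
the tests exploit), but not under general within-segment reordering.

Minimum lengths: the composition encoders need $L \ge 1$ (GAAC) and
$L \ge 2$ (DPC); the profile encoders need every block non-empty and
longer than the largest lag/rank, enforced as
$L \ge 3(\max(\text{lag, rank}) + 1)$ with a clear error.

Feature names are a stable API of the form `ENC.detail`
(`DPC.AC`, `PSETS.slice3.mean.W`, `SGACT.seg2.lag1.K`), so selection
traces remain human-auditable; the default fused 525-name list is
frozen in a golden-file test.

## Feature selection: ERT-RFE

Recursive feature elimination driven by an extremely-randomized-tree
(ERT) ensemble: at each iteration a 250-tree ERT is fit on the
surviving features, features are ranked by mean impurity decrease (the
canonical ERT importance), the subset's stratified cross-validated
accuracy is recorded, and the `step` lowest-ranked features are removed
— ties broken lexicographically, dropping the later name first, so the
trace is deterministic. The subset with the maximal CV accuracy is
selected, ties going to the smaller subset. Design choices where the
procedure is underdetermined:

* the inner scorer is stratified 5-fold accuracy with folds fixed once
  per call — distinct from the outer 10-fold evaluation protocol, so
  subset scores are comparable across iterations and the inner loop
  does not leak the outer folds;
* the elimination step defaults to 1 feature per iteration and accepts
  a fraction of the surviving count for wide matrices;
* `select_per_encoder()` provides the alternative pathway that reduces
  each descriptor block independently and fuses the winners — both
  "select on the fused matrix" and "select per encoder then fuse" are
  legitimate readings of the protocol, so both are implemented.

Note a structural property of the trace: the argmax is taken over
iterations that include the full feature set, so the reported best CV
accuracy can never fall below that of the full set on the same folds.

## Classifiers and evaluation protocol

Three classifiers are supported. `LXGB` is leaf-wise (loss-guided)
gradient boosting with defaults depth 8, learning rate (eta) 0.1, L1
penalty (alpha) 1, L2 penalty (lambda) 1, 500 rounds — the published
working point, with "alpha"/"lambda" read as the L1/L2 regularization
terms and the rate as eta, the standard naming in boosting frameworks.
`RF` and `ERT` default to 500 trees to parallel the boosting estimator
count (their count is otherwise unstated); ERT uses no bootstrap and
one random split per candidate feature. Every fit is seeded and
single-threaded, so identical inputs reproduce identical models
bit-for-bit.

Evaluation is stratified tenfold cross-validation. Threshold metrics
(accuracy, sensitivity, specificity, precision, F-measure, MCC at the
fixed 0.5 threshold) are computed from the confusion counts **pooled
across folds** (micro-average); per-fold reports are retained in
`fold_breakdown` since macro-averaging is the other defensible
convention. MCC uses the standard formula with any zero marginal
defined as 0. AuROC/AuPR come from the pooled scores: the ROC sweeps
all distinct thresholds with tied scores grouped (all-equal scores give
exactly 0.5 by the trapezoid rule) and the PR area uses step-wise
interpolation (each recall increment weighted by the precision reached
at that threshold). Leave-one-out (k = n) is admitted as a boundary
case where stratification is vacuous.

The imbalance ablation draws seeded subsamples at fixed
positive:negative counts — 300:300, 300:600, 300:900 by default — and
cross-validates each, quantifying how a growing negative majority
erodes sensitivity at the fixed threshold.

## The synthetic benchmark

`generate_dataset()` emulates a labeled AFP/non-AFP benchmark:
sequences are drawn residue-by-residue from class-specific distributions
over the five GAAC groups (uniform within a group), lengths uniform on
30–90 residues — typical of the short, single-domain range where
sequence-only AFP prediction is hardest, and long enough for all
three-way partitions at the default lags. `synth_pssm()` emulates the
paired profiles: row $m$ is `pssm_signal` times a one-hot template (+6
at the row residue's column, −2 elsewhere, log-odds magnitudes typical
of a conserved position) plus Gaussian noise (sd 1), rounded to
integers to match the PSI-BLAST ASCII dialect. Class signal therefore
enters at two **independent** levels — composition (driving GAAC/DPC)
and profile (driving the PSSM encoders) — so each encoder family's
discriminative contribution can be tested in isolation.

The `"strong"` preset (group-1 weight 0.45 vs 0.25, profile signal 0.8)
is a clearly separable benchmark; the `"null"` preset (identical
uniform composition, zero profile signal) carries no class information
anywhere. These presets define the package's parameter-recovery
surface: the full pipeline (encode, select, tenfold boosted CV) must
exceed 0.9 pooled accuracy on 300+300 strong-signal records and stay
within [0.4, 0.6] on the null preset. What the synthetic benchmark does
**not** emulate: real AFP family structure, shared evolutionary history
between records, homology-driven train/test leakage, alignment-depth
artifacts in real PSSMs, or realistic length/composition marginals.
Passing the recovery tests demonstrates the machinery is correct and
calibrated, not that real-data headline accuracies transfer; real-PSSM
results additionally depend on the PSI-BLAST search configuration,
which is external to this package.

## Numerical choices and degenerate inputs

* Sigmoid normalization is monotone and bounded; double application is
  an error.
* Non-standard residues (B/J/O/U/X/Z) are dropped by default before
  composition encoding (the encoders are defined over the 20-letter
  alphabet only); a `reject` policy is available. A PSSM whose echoed
  residue column disagrees with the FASTA sequence is a warning, not an
  error, because PSI-BLAST masks low-complexity residues to X.
* All-zero confusion tables, single-class label vectors, empty
  sequences, over-short sequences and rank/lag overruns raise
  immediate, named errors rather than propagating NaN.
* Ties: tied scores are grouped into one ROC operating point; tied
  importances break lexicographically; tied CV accuracies prefer the
  smaller subset.

## Problem sizes used by the test suite

The suite verifies the oracle equivalences on 200 random profiles
(lengths 6–60) and 1000 random confusion tables; the parameter-recovery
surface runs the full pipeline on 300+300 synthetic records with a
fractional elimination step (0.2) down to 50 features — sizes chosen so
the whole protocol, including a 100-repeat feature-recovery experiment
(60-record matrices, 10 features, 3 informative at a 3-SD shift) and a
100-repeat imbalance-direction experiment (80:80 vs 80:240 draws,
sequence-only features, 150-round boosting, 5-fold CV), completes in a
few minutes on one core while leaving the planted effects
unambiguously detectable.

## Known limitations

* Real PSSM generation (PSI-BLAST iterations, database, E-value) is out
  of scope; results on real data inherit whatever search configuration
  produced the profiles.
* The package evaluates at a fixed 0.5 decision threshold; applications
  with asymmetric costs should pick an operating point from the ROC/PR
  curves instead.
* ERT-RFE's selected subset is optimized on cross-validated accuracy
  and, like any wrapper selector, is optimistically biased when the
  same records are reused for final evaluation; held-out assessment
  should use an independent test set via `apply_selection()` on fresh
  data.
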