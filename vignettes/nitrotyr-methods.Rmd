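---
title: "Predicting tyrosine nitration sites from position-specific dipeptide propensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tyrosine nitration sites from position-specific dipeptide propensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrotyr)
```

## The problem

Nitrotyrosine is a post-translational modification in which a tyrosine
residue is nitrated by reactive nitrogen species. Elevated nitrotyrosine
levels accompany inflammatory conditions such as rheumatoid arthritis and
septic shock, so knowing *which* tyrosines of a protein can be nitrated
matters for both mechanism and drug development — but experimental mapping
of nitration sites is slow and expensive. `nitrotyr` is a sequence-only
predictor: given a protein, it scores every tyrosine for its propensity to
be a nitration site.

## Windows, the dummy residue, and the benchmark

Each candidate site is represented by the peptide window of $2\ell + 1$
residues centered on the tyrosine. When the window runs past a protein
terminus, the missing positions are filled with the dummy residue `X`, so a
tyrosine at position 1 still yields a full-length window. A labeled
benchmark is the union of a positive subset $S^+$ (windows whose central Y
is an experimentally confirmed nitration site) and a negative subset $S^-$
(all other tyrosine windows of the same proteins).

Coordinates are 1-based on the protein (that is how site lists are
published); the window's internal index is 0-based with the center at
$\ell$. Duplicate peptide strings are retained — all frequencies below are
occurrence frequencies, and deduplication would bias them. Non-standard
residue letters in input FASTA (`B`, `J`, `O`, `U`, `Z`, `*`, `-`) are
mapped to `X` with a warning rather than rejected, which keeps the pipeline
total over real-world sequence files; `X` then participates in counting
like any other residue.

## The encoder: position-specific dipeptide propensities

Residues are coded $1..20$ by the alphabetical order of their one-letter
codes, with `X` as code 21, giving $21^2 = 441$ possible ordered residue
pairs. A window of $2\ell + 1$ residues has $2\ell$ *dipeptide subsites*:
the overlapping adjacent pairs read left to right. (This is the only
reading under which a 19-mer yields the 18-dimensional feature vector used
throughout; subsites $\ell$ and $\ell+1$ both contain the central Y.)

For each class $c \in \{+,-\}$ the PSDP matrix
$Z^c \in [0,1]^{441 \times 2\ell}$ holds the occurrence frequency of
dipeptide $i$ at subsite $j$ among the class's training windows. Every
window contributes exactly one dipeptide per subsite, so each column sums
to 1. Frequencies are raw relative frequencies — no pseudo-count smoothing,
since the discriminant below only ever *sums* matrix entries and never
takes logs or ratios, so zeros are harmless. An additive `pseudocount`
argument exists for robustness experiments but defaults to 0.

A window's feature vector toward class $c$ is the $2\ell$-vector of matrix
entries at its observed subsite dipeptides. The "ideal" peptide of a class
is the hypothetical window whose every component sits at the upper limit 1.

The single-residue baseline (`encoder = "single"`) replaces dipeptides by
single residues at the $2\ell$ non-central positions (a $21 \times 2\ell$
matrix); it measures what per-position composition alone achieves, and thus
what the pairwise coupling adds.

## The discriminant

The similarity of a window to a class's ideal peptide is the inner product
of its feature vector with the all-ones vector, i.e. the component sum:

$$\Phi^{\pm} = \sum_{j=1}^{2\ell} Z^{\pm}[d_j, j] \in [0, 2\ell],$$

where $d_j$ is the dipeptide observed at subsite $j$. Since feature
components lie in $[0,1]$ and the ideal profile is the all-ones vector, any
similarity monotone in the components reduces to this sum up to a
reparameterization of the threshold, so the component sum is adopted and
documented as the canonical form. The discriminant is

$$\Delta = \Phi^+ - \Phi^- + \xi,$$

and the decision rule is **positive iff $\Delta \ge 0$**. The boundary
$\Delta = 0$ is deliberately resolved toward the positive class and tested
as such; with continuous-valued frequencies ties are measure-zero anyway.

### The adjust parameter $\xi$

$\xi$ is an additive offset that compensates for class imbalance (real
nitration benchmarks have roughly 7 negatives per positive). `tune_xi()`
searches the midpoints between consecutive distinct sorted raw scores, plus
two guard thresholds (one below the minimum, one above the maximum, which
call everything positive or everything negative), and picks the threshold
maximizing overall accuracy; ties are broken by higher MCC, then by smaller
$|\xi|$. Guards are placed at `min - 1` and `max + 1` rather than at
$\pm\infty$ so that the returned $\xi$ is always finite. Midpoints make the
tuned threshold invariant under duplication of the dataset.

Under cross-validation two policies are offered:

* `shared` (default): $\xi$ is tuned once on the full dataset's
  resubstitution scores and shared by all folds; only the matrices are
  re-estimated per fold. This matches reporting a single $\xi$ alongside a
  jackknife result.
* `nested`: $\xi$ is re-tuned inside every fold on the training split only.
  Leakage-free, but quadratic in $n$ for the jackknife; intended for small
  studies of the tuning bias itself.

Evaluation objects record which policy produced them.

## Evaluation

`confusion_metrics()` computes Sn, Sp, Acc and MCC twice — from TP/TN/FP/FN
and from the equivalent "intuitive" formulation in terms of the class sizes
$N^+, N^-$ and the two misclassification counts $N^{+-}, N^{-+}$ — and the
test suite verifies the two agree to $10^{-12}$ on random confusion tables.
When the MCC denominator is zero (everything called one class) the MCC is
reported as 0 with an explicit `mcc_defined = FALSE` flag; the standard
convention, chosen because it is the limit of vanishing association.

The **jackknife** (leave-one-out) is the primary protocol: it yields a
unique, arbitrariness-free result for a given benchmark. Because every
window contributes exactly one count per subsite, leaving a sample out is
an $O(2\ell)$ decrement of its own class's count matrix followed by
renormalization with $n-1$; the whole jackknife is one vectorized pass, and
the test suite proves the decremental update identical to explicit
retraining. **k-fold** cross-validation uses stratified folds from a seeded
shuffle (the fold construction is not canonical, so the seed is recorded in
the result); counts are pooled across folds (micro-averaged) rather than
averaging per-fold metrics, matching how a single jackknife confusion table
is reported. When `k` equals the dataset size the folds are singletons and
k-fold coincides exactly with the jackknife — the suite asserts this
degeneracy.

ROC curves sweep the decision threshold over all distinct observed raw
scores plus a guard (equivalently, sweep $\xi$); a sample scoring exactly
at the threshold is called positive, consistently with the $\Delta \ge 0$
rule. AUC is the trapezoidal area, and equals the normalized Mann–Whitney
$U$ statistic (asserted against both the rank formulation and an
independent ROC implementation). `window_size_sweep()` rebuilds the
benchmark at several half-widths and reports the cross-validated AUC per
$\ell$: enlarging the window helps only while the added flank positions
still carry nitration signal.

## The synthetic generator

`generate_benchmark()` emulates a nitration benchmark: tyrosine-centered
windows whose flanks are drawn from a background distribution over the 20
standard amino acids, with positives additionally receiving planted
position-specific dipeptide enrichments (`motif_spec()`): at subsite $j$
the ordered pair overwrites the background draw with probability $p$,
applied left-to-right so a later overlapping plant overwrites one residue
of an earlier one (documented rather than forbidden). Plants covering the
center must keep Y there. The background deliberately excludes `X` —
padding is a windowing artifact, not a residue — so `X` enters generated
data only through `extract_windows()` on real or generated proteins.

Defaults are the study conditions of a realistic benchmark: 1,044 positive
and 7,669 negative 19-mers ($\ell = 9$, the roughly 1:7.3 imbalance of
curated nitration data), a uniform background, and a fixed moderate motif
(`default_nitration_motif()`) enriching acidic/charged pairs (`DE`, `EY`,
`YD`, `DK`) at the four subsites flanking the center with probabilities
0.2–0.3 — the kind of acidic near-site contrast reported for nitration
sequence neighborhoods. These values were chosen once as a realistic
operating point and are not fitted to anything.

What the generator does *not* emulate: homology-driven redundancy between
windows from related proteins, non-uniform proteome composition, and
correlated multi-site proteins. Passing tests on generated data therefore
demonstrate correctness of the estimator, discriminant and evaluation
machinery under known ground truth — not the field performance of the
predictor on real proteomes, which can only be measured on curated data.

`generate_annotated_proteins()` produces whole proteins with designated
nitration sites (motif planted in protein coordinates at spaced interior
positions) so the FASTA → windows → benchmark path is exercised end to end;
background tyrosines become negatives naturally.

## Reproducing the published operating point

An externally curated benchmark of experimentally confirmed nitration
sites — 1,044 positive and 7,669 negative 19-mers from 546 proteins — is
distributed as a supplementary word-processor document and is not shipped
with the package. To evaluate against it, convert it once to the
four-column TSV dialect of `read_benchmark()` (`protein_id`, `position`,
`peptide`, `label` with 1 = nitrotyrosine) and place it at
`inst/extdata/benchmark_s1.tsv`; the acceptance tests then run the full
$\ell = 9$ jackknife against it. Without the file those two tests fail with
an explicit message — they are not silently skipped.

## Numerical choices and problem sizes

* All count arithmetic is done in doubles where products appear: the MCC
  denominator overflows 32-bit integers already at $n \approx 9{,}000$.
* Column normalization, metric-formulation agreement, and the
  decremental-vs-retrain identity are asserted at $10^{-12}$.
* Model files store frequencies and $\xi$ with 17 significant digits, which
  round-trips IEEE doubles exactly; the save/load cycle is asserted
  byte-identical.
* Test problem sizes were chosen so properties are sharp but cheap: exact
  identities on toys of $n \le 50$, stochastic properties at
  $n = 250$–$5{,}000$ per class with fixed seeds (binomial recovery bounds
  at $n = 5{,}000$, chance-level AUC at $n = 1{,}000$ per class), and the
  full study-scale jackknife ($n = 8{,}713$) which runs in well under a
  second thanks to the decremental update.

## Known limitations

* The predictor is purely sequence-based; structural accessibility of the
  tyrosine, a known determinant of nitration, is outside its scope.
* Accuracy-optimal $\xi$ tuning on a 1:7 imbalanced benchmark tends to
  favor specificity over sensitivity; if balanced operating points are
  needed, fix $\xi$ manually or pick it from the ROC curve.
* `nested` $\xi$ tuning under the jackknife is $O(n^2 \cdot 2\ell)$ and is
  impractical above a few thousand windows.
* The negative class is "every non-annotated tyrosine", so unannotated true
  sites contaminate $S^-$; metrics on real data are accordingly
  conservative.
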