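---
title: "Knowledge-driven feature selection over GO term subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-driven feature selection over GO term subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOwise)
```

## Model and assumptions

GOwise addresses two-class supervised analysis of a gene expression
matrix (P probesets × N samples, labels −1/+1) in which prior biological
knowledge is applied *before* variable selection. The Gene Ontology
supplies the structure: for every GO term of one domain (MF, BP or CC),
the platform annotation defines the set of probesets annotated to the
term, and masking the expression matrix to those rows yields one subset
per term. Subsets overlap by construction — the GO graph is a DAG and a
probeset usually carries several annotations. The analysis stays at the
probeset level throughout; aggregating probesets to genes would require
an averaging scheme that injects its own bias, so none is performed.

Each subset is treated as an independent classification problem:

* **ℓ1ℓ2 route** (large subsets): minimize
  \[(1/n)\,\lVert y - Xw\rVert_2^2 + \tau \lVert w\rVert_1 +
  \mu \lVert w\rVert_2^2\]
  by FISTA (proximal gradient with Nesterov acceleration; the proximal
  operator of the ℓ1 term is coordinate-wise soft-thresholding). The
  support of the solution is the selected variable set; prediction uses a
  ridge-free RLS refit on the support and the sign rule. Model selection
  is nested stratified K-fold cross-validation: inner folds choose τ by
  validation error, outer folds provide the test-error estimate,
  confusion counts and per-variable selection frequencies.
* **RLS route** (small subsets, \(P_X \le N\) by default): no model
  selection is needed; a minimum-norm least-squares classifier is
  cross-validated on the outer folds only, and the subset's variables are
  treated as selected or not wholesale, depending on the significance
  call on the term.

The loss carries a \(1/n\) factor so penalty values are comparable across
fold sizes; this scaling is stated explicitly because the literature on
this family of solvers varies on it, and every internal bound (e.g. the
full-shrinkage value \(\tau_{\max} = 2\max_j |\tfrac1n\sum_i x_{ij}
y_i|\)) is derived under it.

A term is **significant** when its mean outer-fold test error is
*strictly below* the error threshold; a variable of a significant ℓ1ℓ2
term is **properly selected** when its selection frequency is *strictly
above* the frequency threshold. Both inequalities are strict by design —
the thresholds are exclusion bounds, so boundary values fail. For
significant RLS terms all subset variables are properly selected.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `errorThreshold` | 0.30 | significance bound on mean outer CV error (fraction) |
| `freqThreshold` | 0.5 | properly-selected bound, as a fraction of `outerK` |
| `muValues` | 1e-3, 1e-2, 1e-1 | correlation penalties μ (columns standardized, so unitless) |
| `l1Grid` | auto | geometric, 20 values in \[1e-3·τ_max, τ_max\] per outer fold |
| `innerK`, `outerK` | 3, 4 | nested CV fold counts |
| `ratioThreshold` | 1.0 | RLS routing: RLS iff P_X ≤ ratio·N (boundary inclusive) |
| `semanticThreshold` | 0.8 | similarity level of the flat cluster cut |
| `tol`, `maxIter` | 1e-6, 20000 | solver KKT tolerance and iteration cap |

The frequency threshold is expressed as a fraction of the outer fold
count rather than an absolute count so results are comparable across K.
The μ ladder spans three decades because columns are standardized with
training-fold statistics — on that scale the penalties are
size-independent; μ is reported by index (`mu1`, `mu2`, ...) in every
output, and the error estimate is expected to be stable across μ.

## Numerical choices

* **Standardization** uses outer-training-fold means/SDs only, applied
  unchanged to the corresponding test fold — no information leaks from
  test samples. Constant columns keep scale 1.
* **Inner-CV tie-break**: among τ values with equal mean inner error the
  *smallest* penalty (densest model) wins. Resolving towards sparsity
  looks attractive for stability, but it fails in two ways this package's
  own verification exposed: the τ_max grid endpoint, tied at the
  inner-error plateau, refits to an *empty* support on the outer fold
  (a null model scoring ~50% on a perfectly separable subset), and a
  sparser tie drops members of the correlated variable groups that μ is
  designed to keep together. The densest minimizer avoids both; the
  extra noise variables it admits are inconsistent across folds and are
  removed by the selection-frequency filter downstream.
* **Empty support**: if the chosen τ shrinks everything to zero, the
  outer model predicts the majority training label (ties to +1); the
  split still contributes an error and confusion counts.
* **Convergence** is declared on the subgradient (KKT) residual, not on
  step size, so "converged" means verified optimality within `tol`;
  non-convergence is a warning, never a silent result.
* **RLS with zero ridge** uses the SVD pseudo-inverse, i.e. the
  minimum-norm solution on rank-deficient designs; the regularized normal
  equations use \((X^\top X + n\lambda I)\) for consistency with the 1/n
  loss.
* **Sign ties** (score exactly 0) classify as +1 by convention.
* **MCC** with any zero denominator factor is defined as 0.
* **Stratified folds** deal shuffled class members round-robin, so every
  fold contains both classes whenever each class has ≥ K samples; a
  smaller class is a hard stratification error.

## Determinism and parallelism

Every task (one term's nested CV) derives a private RNG seed from the
master seed and the term id, so fold assignments and results are
identical whatever the worker count or task order. The experiment phase
writes one JSON result per term into the ensemble; the postprocess phase
is a pure function of those files and reproduces its outputs
byte-identically. The two phases are separated on disk (an ensemble is
only postprocessable once marked complete), mirroring the
experiment/postprocess application split.

## Semantic layer

Information content uses the annotation corpus induced by the
term→probeset map itself (each direct probeset annotation counts once):
IC(t) = −log(annotations subsumed by t / annotations subsumed by the
root), with "subsumed" summed over the term and its descendants. This
default keeps the package fully offline; an external association table
can replace it when available, and the choice only shifts IC values, not
the structure of the computation. Natural logarithms are used; since the
Resnik matrix is normalized to its maximum observed entry (diagonal
included), the log base cancels and clustering is invariant under any
positive rescaling of IC. Terms subsuming zero annotations have
undefined IC and are excluded from clustering with a warning, never
silently. Clustering is agglomerative with average linkage on distance
1 − similarity, cut at 1 − threshold; average linkage is the default
because single linkage chains dissimilar terms together and complete
linkage over-fragments shallow DAGs, but both remain available.

## What the synthetic generator emulates — and what it does not

`makeBundle()` produces the full input battery: Gaussian (optionally
heavy-tailed t₃) expression noise, a random single-domain DAG (rooted
tree plus extra is_a edges), term sizes log-uniform in [3, 200] so both
learning routes are exercised, balanced labels, platform annotations
with a slice of outdated gene symbols resolvable through the HGNC-style
previous-symbols column, and benchmark lists of the informative genes
plus decoys. Informative probesets get a class-mean shift expressed in
noise SDs, so "effect 3" means a 3σ gap.

The canonical verification conditions are 40 samples, one informative
term with 5 informative probesets at 3σ, outer K = 4. Because subsets
overlap, noise terms can contain informative probesets; the manifest
lists these "contaminated" terms so recovery statistics can exclude them
from the pure-noise pool — flagging a contaminated term is correct
behavior, not a false positive.

What the generator does **not** model: probe-level microarray physics,
normalization artifacts, batch effects, correlated noise between
probesets of one gene, unbalanced designs beyond the class-balance
parameter, and annotation errors other than outdated symbols. Passing
tests therefore demonstrate the statistical machinery under clean,
controlled signal — not robustness to every pathology of real chips.

## Verification problem sizes

The package's own verification (test suite and `scripts/acceptance.R`)
uses desk-scale problems chosen to exercise every code path while
keeping a full run in minutes: 200 random solver instances (n ≤ 40,
p ≤ 60) against an independent convex-optimization oracle, 20 recovery
replicates of the canonical bundle with a single μ = 0.5 (chosen high
because the study's target is co-selection of the correlated
informative group) and a 10-point τ grid, 50 pure-noise subsets
(60 × 40) for error calibration, and a
15-term enumerated toy DAG for the semantic layer. These sizes are the
package's reference conditions for verification.

## Known limitations

* Two-class problems only; regression and multi-class settings are out
  of scope.
* ℓ1ℓ2FS is the only embedded selector; the per-term task interface is
  the plug point for alternatives, but none are shipped.
* No multiple-testing correction across terms — significance is a fixed
  error threshold per term, by design.
* The relational store is a directory of TSV tables behind a small query
  API; it favors transparency and diffability over transactional
  guarantees.
* GO is read from OBO or a plain edge list; only `is_a` edges build the
  DAG by default (`part_of` can be included when an edge list provides
  it).
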