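# GOwise

Knowledge-driven feature selection over Gene Ontology term subsets for
two-class gene expression studies.

## The problem

The standard route from an expression matrix to biology selects a gene
signature first (t-tests, embedded methods, ...) and judges it against
prior knowledge only afterwards, through enrichment analysis. That late
mapping is fragile: it depends on selection thresholds, on annotation
versions, and it can silently discard any biological function whose genes
did not make the signature.

GOwise turns the order around. The prior knowledge is applied *before*
selection: the P × N expression matrix (P probesets, N samples with
labels y ∈ {−1, +1}) is masked once per Gene Ontology term, giving one
P_X × N submatrix per term from a chosen GO domain (MF, BP or CC). Each
term subset is then analyzed as its own supervised classification
problem, and the interpretable output is a list of *significant GO
terms*, each carrying its own small signature of *properly selected*
probesets.

## The method

For each term subset the package runs embedded ℓ1ℓ2-regularized feature
selection, minimizing

    (1/n) ‖y − Xw‖₂² + τ‖w‖₁ + μ‖w‖₂²

by accelerated iterative soft-thresholding (FISTA). The ℓ1 weight τ
drives sparsity; the correlation parameter μ controls how many correlated
variables enter the support together. Model selection is a full nested
K-fold cross-validation: inner folds pick τ (ties resolved towards the
sparsest model), outer folds yield unbiased test errors, confusion
counts, and per-variable selection frequencies. Subsets with at most
about as many variables as samples skip model selection and are
classified with plain regularized least squares (RLS, ridge weight 0).

Downstream, a term is **significant** when its mean outer-fold test error
is strictly below a threshold (default 30%); a variable of a significant
ℓ1ℓ2 term is **properly selected** when its selection frequency exceeds a
fraction of the outer folds (default 1/2); for significant RLS terms all
variables count as selected. Unified per-μ term lists carry pooled
confusion counts and the Matthews correlation coefficient. Significant
terms are clustered by Resnik semantic similarity (information content of
the most-informative common ancestor, normalized to the maximum observed
value) and drawn on the minimal ancestor subgraph as Graphviz DOT, one
color per cluster. Recovery of benchmark gene/term lists is scored as
coverage, with the term denominator restricted to the analyzed GO domain.

## Worked example

Everything runs offline: the fixture generator emits a complete input
bundle (expression TSV, labels, platform annotations, gene-name table,
OBO graph, benchmark lists, ready-made config).

```r
library(GOwise)

spec <- fixtureSpec(nSamples = 20L, nProbesets = 60L, nTerms = 8L,
                    termSizeRange = c(3L, 40L),
                    informativeTerms = list(
                      list(size = 30L, nInformative = 4L, effect = 3)),
                    seed = 33L)
b <- makeBundle(spec, "bundle")
b$manifest_data$informative_terms
#> [1] "GO:0000002"

runExperiment(b$config, "ensemble", seed = 9L)
#> [experiment] GEDM: 60 probesets x 20 samples
#> [experiment] labels: 10 / 10 per class
#> [experiment] subsets: 7 (5 RLS, 2 L1L2FS)
#> [experiment] discovery: 7 term results written

pp <- runPostprocess("ensemble",
                     benchmarkGenes = b$benchmark_genes,
                     benchmarkTerms = b$benchmark_terms)
head(subset(pp$verdicts, significant)[, 1:4], 4)
#>      term_id source technique error_estimate
#> 1 GO:0000002    mu1    L1L2FS     0.00000000
#> 2 GO:0000002    mu2    L1L2FS     0.04166667
#> 3 GO:0000002    mu3    L1L2FS     0.04166667
#> 6 GO:0000005    RLS       RLS     0.16666667

pp$unified$mu1[, c("term_id", "total_variables", "n_properly_selected",
                   "error_estimate", "mcc")]
#>      term_id total_variables n_properly_selected error_estimate       mcc
#> 1 GO:0000002              30                  12      0.0000000 1.0000000
#> 4 GO:0000008              30                   2      0.0000000 1.0000000
#> 2 GO:0000005               7                   7      0.1666667 0.7035265
#> 3 GO:0000006               5                   5      0.1875000 0.6000000

pp$coverage[pp$coverage$source == "mu1", ]
#>   source  kind       restriction n_benchmark n_covered coverage
#> 1    mu1 genes               all          16         6    0.375
#> 2    mu1 terms domain-restricted           5         2    0.400
```

The planted informative term `GO:0000002` comes back significant with a
cross-validated error of 0 at μ index 1 (its four shifted probesets
separate the classes by 3 noise SDs); the further significant terms are
the ones that share those informative probesets through the overlapping
GO structure, and the unified list pools each term's outer-fold
confusion counts into an MCC.
`ensemble/postprocess/` then holds the per-μ significant and unified term
lists, properly-selected variable tables with HGNC-verified symbols,
selection histograms, error statistics, the cluster assignment, the DOT
subgraph and the coverage report — all plain TSV/DOT.

Command-line entry points wrapping these two calls live in `inst/cli/`
(`experiment.R`, `postprocess.R`).

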