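# Shared helpers: handcrafted tiny DAGs, labeled expression objects and the
# independent convex-optimization oracle for the l1l2 solver.

# A fixed five-term MF DAG:   root <- A <- B, root <- C, A <- D
#  (edges child -> parent)
tinyDagFile <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    term = c("GO:ROOT", "GO:A", "GO:B", "GO:C", "GO:D"),
    parent = c("", "GO:ROOT", "GO:A", "GO:ROOT", "GO:A"),
    domain = "MF")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tinyDag <- function() readGODag(tinyDagFile(), format = "edge-list")

# Labeled SummarizedExperiment from a matrix and -1/+1 labels.
labeledSe <- function(vals, y) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals))
  se$label <- y
  se
}

# Gaussian noise matrix with named dims.
noiseMatrix <- function(p, n, sd = 1, prefix = "PS") {
  matrix(rnorm(p * n, 0, sd), nrow = p,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(p)),
                         sprintf("S%03d", seq_len(n))))
}

# Balanced -1/+1 labels for n samples (n even), in fixed order.
balancedLabels <- function(n) rep(c(-1, 1), length.out = n)

# Independent oracle for the l1l2 objective via glmnet:
# our (1/n)||y-Xw||^2 + l1|w|_1 + mu||w||^2 halves to glmnet's problem with
# lambda = l1/2 + mu, alpha = (l1/2)/lambda (no intercept, no internal
# standardization).
glmnetOracle <- function(X, y, l1, mu) {
  lambda <- l1 / 2 + mu
  stopifnot(lambda > 0)
  alpha <- (l1 / 2) / lambda
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14,
                        maxit = 1e7)
  as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = X,
                                 y = y)[-1])
}

# A minimal SelectionResult built by hand (for postprocess unit tests).
fakeResult <- function(termId, technique, probesets, outerK,
                       testErrors, confusions, selectedPerSplit) {
  splits <- lapply(seq_len(outerK), function(k) list(
    split_index = k,
    selected_variables = selectedPerSplit[[k]],
    chosen_l1 = NA_real_,
    test_error = testErrors[k],
    train_error = 0,
    confusion = confusions[[k]]))
  entry <- GOwise:::muEntry(0.01, splits, probesets, outerK)
  key <- if (technique == "RLS") "RLS" else "mu1"
  new("SelectionResult", termId = termId, technique = technique,
      perMu = setNames(list(entry), key), probesetIds = probesets,
      outerK = as.integer(outerK), nSamples = 40L)
}
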