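# Nested cross-validated model selection per GO-term subset.

#' Construct a solver configuration
#'
#' Defaults: three correlation penalties on a logarithmic ladder (columns
#' are standardized, so the penalty scale is data-independent), an
#' automatic geometric l1 grid of 20 values per outer training fold from
#' 1e-3 * l1_max up to l1_max (the full-shrinkage bound), 3 inner and 4
#' outer stratified folds.
#'
#' @param muValues squared-l2 (correlation) penalties
#' @param l1Grid explicit l1 grid; empty = automatic per-fold grid
#' @param nL1,l1MinRatio automatic grid shape
#' @param innerK,outerK fold counts
#' @param tol,maxIter l1l2 solver controls
#' @param seed master seed; all folds and task streams derive from it
#' @param standardize center/scale columns with training-fold statistics
#' @return a [SolverConfig-class]
#' @export
solverConfig <- function(muValues = c(1e-3, 1e-2, 1e-1),
                         l1Grid = numeric(), nL1 = 20L, l1MinRatio = 1e-3,
                         innerK = 3L, outerK = 4L, tol = 1e-6,
                         maxIter = 20000L, seed = 101L,
                         standardize = TRUE) {
  obj <- new("SolverConfig", muValues = as.numeric(muValues),
             l1Grid = as.numeric(l1Grid), nL1 = as.integer(nL1),
             l1MinRatio = as.numeric(l1MinRatio),
             innerK = as.integer(innerK), outerK = as.integer(outerK),
             tol = as.numeric(tol), maxIter = as.integer(maxIter),
             seed = as.integer(seed), standardize = standardize)
  validObject(obj)
  obj
}

# Stratified fold assignment: permute within class, deal round-robin.
# Guarantees both classes in every fold when each class has >= K members.
stratifiedFolds <- function(y, K) {
  if (min(table(y)) < K)
    stop("stratification error: a class has fewer than K = ", K,
         " samples")
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

# Column standardization with training statistics (constant columns keep
# scale 1); returns train/test matrices on the train scale.
standardizePair <- function(Xtr, Xte, enabled = TRUE) {
  if (!enabled) return(list(train = Xtr, test = Xte))
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(Xte, 2L, mu), 2L, sdv, "/"))
}

# Majority label of a training vector, ties to +1.
majorityLabel <- function(y) if (sum(y == 1) >= sum(y == -1)) 1 else -1

# Two-stage prediction: l1l2 support, then RLS refit (lambda = 0) on the
# support; empty support predicts the majority training label.
fitPredictL1L2 <- function(Xtr, ytr, Xte, l1, mu, tol, maxIter, w0 = NULL) {
  w <- suppressWarnings(l1l2Solve(Xtr, ytr, l1 = l1, mu = mu, tol = tol,
                                  maxIter = maxIter, w0 = w0))
  support <- which(w != 0)
  if (length(support) == 0L) {
    lab <- majorityLabel(ytr)
    predTe <- rep(lab, nrow(Xte))
    predTr <- rep(lab, nrow(Xtr))
  } else {
    wr <- rlsSolve(Xtr[, support, drop = FALSE], ytr, lam = 0)
    predTe <- classifyLabels(wr, Xte[, support, drop = FALSE])
    predTr <- classifyLabels(wr, Xtr[, support, drop = FALSE])
  }
  list(support = support, w = w, predTest = predTe, predTrain = predTr)
}

# Summary statistics block shared by both task runners.
muEntry <- function(mu, splits, probesetIds, outerK) {
  testErr <- vapply(splits, `[[`, numeric(1), "test_error")
  trainErr <- vapply(splits, `[[`, numeric(1), "train_error")
  freq <- setNames(integer(length(probesetIds)), probesetIds)
  for (s in splits) {
    sel <- s$selected_variables
    freq[sel] <- freq[sel] + 1L
  }
  list(mu = mu, splits = splits, frequencies = freq,
       mean_test_error = mean(testErr), sd_test_error = sd(testErr),
       median_test_error = median(testErr),
       mean_train_error = mean(trainErr), sd_train_error = sd(trainErr))
}

#' Run the embedded l1l2 feature-selection task on one subset
#'
#' Full model selection with two nested stratified K-fold cross-validation
#' loops.  For each outer fold, the inner loop picks the l1 penalty
#' minimizing mean inner validation error (ties broken towards the
#' smallest penalty, i.e. the densest model); the selected-variable set is the
#' support of the l1l2 solution at that penalty on the outer training
#' data, and prediction on the outer test fold (after an RLS refit on the
#' support) yields the test error and confusion counts.  The whole loop is
#' repeated for every mu, and per-variable selection frequencies are
#' tallied across outer splits.
#'
#' @param subset a [TermSubset-class] routed to L1L2FS
#' @param labels named -1/+1 vector covering the subset's samples
#' @param cfg a [SolverConfig-class]
#' @return a [SelectionResult-class]
#' @export
runL1L2Task <- function(subset, labels, cfg) {
  vals <- subsetValues(subset)
  X <- t(vals)                      # samples x variables
  y <- unname(labels[rownames(X)])
  if (anyNA(y)) stop("labels missing for some samples of subset ",
                     termId(subset))
  probesetIds <- colnames(X)
  set.seed(deriveSeed(cfg@seed, paste0("l1l2:", termId(subset))))
  outerFold <- stratifiedFolds(y, cfg@outerK)
  innerFoldSets <- lapply(seq_len(cfg@outerK), function(k)
    stratifiedFolds(y[outerFold != k], cfg@innerK))
  perMu <- list()
  for (m in seq_along(cfg@muValues)) {
    mu <- cfg@muValues[m]
    splits <- vector("list", cfg@outerK)
    for (k in seq_len(cfg@outerK)) {
      tr <- outerFold != k
      std <- standardizePair(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                             cfg@standardize)
      Xtr <- std$train; Xte <- std$test
      ytr <- y[tr]; yte <- y[!tr]
      grid <- if (length(cfg@l1Grid)) sort(cfg@l1Grid, decreasing = TRUE)
        else sort(geomSeq(cfg@l1MinRatio * l1Max(Xtr, ytr),
                          l1Max(Xtr, ytr), cfg@nL1), decreasing = TRUE)
      innerFold <- innerFoldSets[[k]]
      innerErr <- matrix(NA_real_, nrow = cfg@innerK, ncol = length(grid))
      for (j in seq_len(cfg@innerK)) {
        itr <- innerFold != j
        istd <- standardizePair(Xtr[itr, , drop = FALSE],
                                Xtr[!itr, , drop = FALSE],
                                cfg@standardize)
        w0 <- NULL
        for (g in seq_along(grid)) {
          fit <- fitPredictL1L2(istd$train, ytr[itr], istd$test,
                                l1 = grid[g], mu = mu, tol = cfg@tol,
                                maxIter = cfg@maxIter, w0 = w0)
          w0 <- fit$w
          innerErr[j, g] <- errorRate(fit$predTest, ytr[!itr])
        }
      }
      meanInner <- colMeans(innerErr)
      # ties resolved towards the smallest l1 (densest model): the l1_max
      # endpoint refits to an empty support on the outer fold, and a
      # sparser tie would drop members of correlated groups that mu is
      # meant to keep together
      ties <- which(meanInner <= min(meanInner) + 1e-12)
      best <- ties[length(ties)]
      fit <- fitPredictL1L2(Xtr, ytr, Xte, l1 = grid[best], mu = mu,
                            tol = cfg@tol, maxIter = cfg@maxIter)
      conf <- confusionCounts(fit$predTest, yte)
      splits[[k]] <- list(
        split_index = k,
        selected_variables = probesetIds[fit$support],
        chosen_l1 = grid[best],
        test_error = errorRate(fit$predTest, yte),
        train_error = errorRate(fit$predTrain, ytr),
        confusion = conf)
    }
    perMu[[paste0("mu", m)]] <- muEntry(mu, splits, probesetIds,
                                        cfg@outerK)
  }
  res <- new("SelectionResult", termId = termId(subset),
             technique = "L1L2FS", perMu = perMu,
             probesetIds = probesetIds, outerK = cfg@outerK,
             nSamples = length(y))
  attr(res, "outerFold") <- outerFold
  validObject(res)
  res
}

#' Run the plain RLS task on one small subset
#'
#' Outer stratified K-fold cross-validation only: no inner loop, no
#' penalty grid, ridge weight fixed at zero (minimum-norm least squares).
#' All variables count as selected in every split; whether they survive is
#' decided downstream by the significance call on the term.  The result
#' carries a single pseudo-mu entry keyed \code{"RLS"}.
#'
#' @inheritParams runL1L2Task
#' @param subset a [TermSubset-class] routed to RLS
#' @return a [SelectionResult-class]
#' @export
runRLSTask <- function(subset, labels, cfg) {
  vals <- subsetValues(subset)
  X <- t(vals)
  y <- unname(labels[rownames(X)])
  if (anyNA(y)) stop("labels missing for some samples of subset ",
                     termId(subset))
  probesetIds <- colnames(X)
  set.seed(deriveSeed(cfg@seed, paste0("rls:", termId(subset))))
  outerFold <- stratifiedFolds(y, cfg@outerK)
  splits <- vector("list", cfg@outerK)
  for (k in seq_len(cfg@outerK)) {
    tr <- outerFold != k
    std <- standardizePair(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                           cfg@standardize)
    w <- rlsSolve(std$train, y[tr], lam = 0)
    predTe <- classifyLabels(w, std$test)
    predTr <- classifyLabels(w, std$train)
    splits[[k]] <- list(
      split_index = k,
      selected_variables = probesetIds,
      chosen_l1 = NA_real_,
      test_error = errorRate(predTe, y[!tr]),
      train_error = errorRate(predTr, y[tr]),
      confusion = confusionCounts(predTe, y[!tr]))
  }
  perMu <- list(RLS = muEntry(NA_real_, splits, probesetIds, cfg@outerK))
  res <- new("SelectionResult", termId = termId(subset), technique = "RLS",
             perMu = perMu, probesetIds = probesetIds, outerK = cfg@outerK,
             nSamples = length(y))
  attr(res, "outerFold") <- outerFold
  validObject(res)
  res
}

#' Run the knowledge-discovery step on all subsets
#'
#' Dispatches each subset to its routed technique.  Tasks are independent
#' (each derives its own RNG stream from the master seed and term id), so
#' results are identical for any worker count and task order.
#'
#' @param subsets named list of [TermSubset-class]
#' @param labels named -1/+1 vector
#' @param cfg a [SolverConfig-class]
#' @param workers number of parallel workers (forked; 1 = sequential)
#' @return named list of [SelectionResult-class]
#' @export
runDiscovery <- function(subsets, labels, cfg, workers = 1L) {
  runOne <- function(s) {
    if (technique(s) == "RLS") runRLSTask(s, labels, cfg)
    else runL1L2Task(s, labels, cfg)
  }
  res <- if (workers > 1L)
    parallel::mclapply(subsets, runOne, mc.cores = workers,
                       mc.preschedule = FALSE)
  else lapply(subsets, runOne)
  err <- vapply(res, function(r) inherits(r, "try-error") ||
                  !methods::is(r, "SelectionResult"), logical(1))
  if (any(err))
    stop("discovery failed for term(s): ",
         paste(names(res)[err], collapse = ", "))
  res
}
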