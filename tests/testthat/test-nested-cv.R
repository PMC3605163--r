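mkSubset <- function(vals, technique) {
  new("TermSubset", termId = "GO:TEST", values = vals,
      technique = technique)
}

test_that("l1l2 task keeps the loop contract and confusion consistency", {
  set.seed(10)
  vals <- noiseMatrix(50, 24)
  labels <- setNames(balancedLabels(24)[sample(24)], colnames(vals))
  cfg <- solverConfig(muValues = c(1e-2, 1e-1), nL1 = 6L, innerK = 3L,
                      outerK = 4L, tol = 1e-5, seed = 21L)
  res <- suppressWarnings(runL1L2Task(mkSubset(vals, "L1L2FS"), labels, cfg))
  expect_s4_class(res, "SelectionResult")
  expect_named(perMu(res), c("mu1", "mu2"))
  for (key in names(perMu(res))) {
    entry <- perMu(res, key)
    expect_length(entry$splits, 4L)
    for (s in entry$splits) {
      # confusion counts sum to the outer test-fold size and reproduce
      # the test error
      expect_equal(sum(s$confusion), 6)
      expect_equal(s$test_error,
                   (s$confusion[["FP"]] + s$confusion[["FN"]]) /
                     sum(s$confusion))
    }
    expect_true(all(entry$frequencies >= 0 & entry$frequencies <= 4))
    # statistics are recomputable from the stored splits
    te <- vapply(entry$splits, `[[`, numeric(1), "test_error")
    expect_equal(entry$mean_test_error, mean(te))
    expect_equal(entry$sd_test_error, sd(te))
    expect_equal(entry$median_test_error, median(te))
  }
})

test_that("a perfectly separating variable is selected in every split", {
  set.seed(11)
  n <- 40
  y <- balancedLabels(n)[sample(n)]
  vals <- noiseMatrix(21, n)
  vals[1, ] <- y * 2 + rnorm(n, 0, 0.5)   # gap 4 SD of its noise
  labels <- setNames(y, colnames(vals))
  cfg <- solverConfig(muValues = 1e-2, nL1 = 8L, innerK = 3L, outerK = 4L,
                      tol = 1e-5, seed = 22L)
  res <- suppressWarnings(runL1L2Task(mkSubset(vals, "L1L2FS"), labels, cfg))
  entry <- perMu(res, "mu1")
  expect_equal(unname(entry$frequencies[rownames(vals)[1]]), 4L)
  expect_lte(entry$mean_test_error, 0.1)
})

test_that("RLS task runs the outer loop only with a single RLS entry", {
  set.seed(12)
  n <- 24
  y <- balancedLabels(n)[sample(n)]
  vals <- noiseMatrix(2, n)
  vals[1, ] <- y * 3 + rnorm(n, 0, 0.3)
  vals[2, ] <- -y * 3 + rnorm(n, 0, 0.3)
  labels <- setNames(y, colnames(vals))
  cfg <- solverConfig(outerK = 4L, seed = 23L)
  res <- runRLSTask(mkSubset(vals, "RLS"), labels, cfg)
  expect_equal(technique(res), "RLS")
  expect_named(perMu(res), "RLS")
  entry <- perMu(res, "RLS")
  expect_length(entry$splits, 4L)
  # separable 2-variable subset: zero error, all frequencies = outerK
  expect_equal(entry$mean_test_error, 0)
  expect_equal(unname(entry$frequencies), c(4L, 4L))
})

test_that("tasks are deterministic and invariant to worker count", {
  set.seed(13)
  vals1 <- noiseMatrix(30, 20, prefix = "A")
  vals2 <- noiseMatrix(8, 20, prefix = "B")
  labels <- setNames(balancedLabels(20), colnames(vals1))
  subsets <- list(A = mkSubset(vals1, "L1L2FS"), B = mkSubset(vals2, "RLS"))
  subsets$A@termId <- "A"; subsets$B@termId <- "B"
  cfg <- solverConfig(muValues = 1e-2, nL1 = 5L, innerK = 2L, outerK = 4L,
                      tol = 1e-5, seed = 77L)
  r1 <- suppressWarnings(runDiscovery(subsets, labels, cfg, workers = 1L))
  r2 <- suppressWarnings(runDiscovery(rev(subsets), labels, cfg,
                                      workers = 2L))
  for (nm in names(r1))
    expect_equal(GOwise:::resultToList(r1[[nm]]),
                 GOwise:::resultToList(r2[[nm]]))
  # rerun with identical config reproduces identical results
  r3 <- suppressWarnings(runDiscovery(subsets, labels, cfg, workers = 1L))
  expect_equal(lapply(r1, GOwise:::resultToList),
               lapply(r3, GOwise:::resultToList))
})

test_that("stratification requires K members per class", {
  set.seed(14)
  vals <- noiseMatrix(5, 8)
  y <- c(rep(1, 6), rep(-1, 2))
  labels <- setNames(y, colnames(vals))
  cfg <- solverConfig(outerK = 4L, seed = 1L)
  expect_error(runRLSTask(mkSubset(vals, "RLS"), labels, cfg),
               "stratification")
  # stratified folds carry both classes in every fold when feasible
  yb <- balancedLabels(16)
  set.seed(15)
  fold <- GOwise:::stratifiedFolds(yb, 4L)
  for (k in 1:4) expect_setequal(unique(yb[fold == k]), c(-1, 1))
})
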