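smallSpec <- function(seed, informative = list(
                        list(size = 10L, nInformative = 3L, effect = 3))) {
  fixtureSpec(nSamples = 20L, nProbesets = 40L, nTerms = 8L,
              termSizeRange = c(3L, 15L), informativeTerms = informative,
              seed = seed)
}

test_that("a fixed seed yields a byte-identical bundle", {
  d1 <- tempfile("b1"); d2 <- tempfile("b2")
  b1 <- makeBundle(smallSpec(7L), d1)
  b2 <- makeBundle(smallSpec(7L), d2)
  for (nm in c("gedm", "labels", "annotations", "gene_names", "go",
               "benchmark_genes", "benchmark_terms", "manifest")) {
    expect_identical(readLines(b1[[nm]]), readLines(b2[[nm]]),
                     label = paste("file", nm))
  }
  # a different seed changes the expression values
  b3 <- makeBundle(smallSpec(8L), tempfile("b3"))
  expect_false(identical(readLines(b1$gedm), readLines(b3$gedm)))
})

test_that("spec validation rejects inconsistent informative terms", {
  expect_error(fixtureSpec(informativeTerms = list(
    list(size = 4L, nInformative = 9L, effect = 3))), "exceeds term size")
  expect_error(fixtureSpec(informativeTerms = list(
    list(size = 4L, nInformative = 2L, effect = -1))), "effect")
})

test_that("zero effect produces no separation beyond chance", {
  b <- makeBundle(smallSpec(21L, informative = list()), tempfile("b"))
  y <- b$labels_vec
  # two-sample t statistic for every probeset; under pure noise the
  # p < 0.01 exceedance rate stays near its nominal level
  pvals <- apply(b$values, 1, function(x)
    t.test(x[y == 1], x[y == -1])$p.value)
  expect_lt(mean(pvals < 0.01), 0.10)
})

test_that("informative probesets carry the specified class-mean gap", {
  b <- makeBundle(smallSpec(22L), tempfile("b"))
  y <- b$labels_vec
  inf <- b$manifest_data$informative_probesets
  expect_length(inf, 3L)
  gaps <- apply(b$values[inf, , drop = FALSE], 1, function(x)
    mean(x[y == 1]) - mean(x[y == -1]))
  # sample gap around 3 noise SDs (SE of the gap ~ sqrt(4/20) ~ 0.45)
  expect_true(all(abs(gaps - 3) < 1.5))
  # non-informative probesets stay near zero gap
  noise <- setdiff(rownames(b$values), inf)
  gapsN <- apply(b$values[noise, ], 1, function(x)
    mean(x[y == 1]) - mean(x[y == -1]))
  expect_lt(max(abs(gapsN)), 2)
})

test_that("toy DAG manifest is a faithful enumeration oracle", {
  toy <- makeToyDag(9, seed = 5L)
  expect_equal(unname(toy$expectedIC[toy$terms$id[1]]), 0)  # root IC 0
  # every non-root term has at least one parent
  expect_setequal(setdiff(toy$terms$id, toy$edges$child), toy$terms$id[1])
  # acyclic by construction and accepted by the DAG validator
  expect_s4_class(toy$dag, "GODag")
  # manifest IC values match the package computation
  ic <- suppressWarnings(computeIC(toy$dag, toy$corpus, "MF"))
  expect_equal(ic[names(toy$expectedIC)], toy$expectedIC)
})

test_that("bundle config and files are consumable by the ingest layer", {
  b <- makeBundle(smallSpec(23L), tempfile("b"))
  se <- attachLabels(readGEDM(b$gedm),
                     readLabels(b$labels, c(case = 1, control = -1)))
  expect_equal(dim(se), c(40L, 20L))
  dag <- readGODag(b$go, format = "obo")
  expect_equal(nrow(goTerms(dag)), 8L)
  anno <- readAnnotations(b$annotations)
  map <- buildTermProbesetMap(anno, dag, "MF", probesets = rownames(se))
  expect_gt(length(termToProbesets(map)), 0L)
  # term sizes in the manifest match the generated annotation
  fwd <- termToProbesets(map)
  sizes <- b$manifest_data$term_sizes
  for (t in names(fwd))
    expect_equal(length(fwd[[t]]), sizes[[t]])
})
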