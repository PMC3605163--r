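# Tiny annotated DAG used across the semantic tests:
#   ROOT <- A <- B, ROOT <- C, A <- D ; direct counts chosen so every term
#   subsumes at least one annotation.
semFixture <- function() {
  dag <- tinyDag()
  corpus <- c(`GO:ROOT` = 1, `GO:A` = 1, `GO:B` = 2, `GO:C` = 3, `GO:D` = 1)
  list(dag = dag, corpus = corpus)
}

test_that("information content follows the subsumed-annotation ratio", {
  fx <- semFixture()
  ic <- computeIC(fx$dag, fx$corpus, "MF")
  total <- sum(fx$corpus)                  # root subsumes everything
  expect_equal(unname(ic["GO:ROOT"]), 0)
  # exhaustive descendant enumeration oracle
  expect_equal(unname(ic["GO:A"]), -log((1 + 2 + 1) / total))
  expect_equal(unname(ic["GO:B"]), -log(2 / total))
  expect_equal(unname(ic["GO:C"]), -log(3 / total))
  # monotone along every is_a edge (child at least as informative)
  edges <- rbind(c("GO:A", "GO:ROOT"), c("GO:B", "GO:A"),
                 c("GO:C", "GO:ROOT"), c("GO:D", "GO:A"))
  for (i in seq_len(nrow(edges)))
    expect_gte(ic[edges[i, 1]], ic[edges[i, 2]])
})

test_that("terms subsuming zero annotations get undefined IC", {
  dag <- tinyDag()
  corpus <- c(`GO:B` = 2, `GO:C` = 1)      # A subsumes B; D subsumes none
  expect_warning(ic <- computeIC(dag, corpus, "MF"), "undefined")
  expect_true(is.na(ic["GO:D"]))
  expect_false(is.na(ic["GO:A"]))
})

test_that("Resnik similarity is the IC of the best common ancestor", {
  fx <- semFixture()
  ic <- computeIC(fx$dag, fx$corpus, "MF")
  # self-similarity equals own IC
  expect_equal(resnikSimilarity(fx$dag, ic, "GO:B", "GO:B"),
               unname(ic["GO:B"]))
  # siblings whose only shared ancestor is the root: similarity 0
  expect_equal(resnikSimilarity(fx$dag, ic, "GO:A", "GO:C"), 0)
  # shared mid-level ancestor A: brute force over the common-ancestor set
  common <- intersect(c("GO:B", "GO:A", "GO:ROOT"),
                      c("GO:D", "GO:A", "GO:ROOT"))
  expect_equal(resnikSimilarity(fx$dag, ic, "GO:B", "GO:D"),
               max(ic[common]))
  # MICA bound on every pair
  ids <- names(ic)
  for (i in ids) for (j in ids)
    expect_lte(resnikSimilarity(fx$dag, ic, i, j), min(ic[i], ic[j]) + 1e-12)
})

test_that("similarity matrix is symmetric, normalized, and recomputable", {
  fx <- semFixture()
  ic <- computeIC(fx$dag, fx$corpus, "MF")
  terms <- c("GO:A", "GO:B", "GO:C", "GO:D")
  S <- buildSimilarityMatrix(fx$dag, ic, terms)
  expect_equal(S, t(S))
  expect_equal(max(S), 1)
  expect_true(all(S >= 0 & S <= 1))
  # elementwise recomputation oracle
  raw <- outer(terms, terms, Vectorize(function(a, b)
    resnikSimilarity(fx$dag, ic, a, b)))
  expect_equal(unname(S), raw / max(raw), ignore_attr = TRUE)
  # clustering input is invariant under positive rescaling pre-normalization
  S2 <- buildSimilarityMatrix(fx$dag, ic * 3, terms)
  expect_equal(unname(S2), unname(S))
})

test_that("degenerate all-zero similarity is returned unnormalized", {
  # chain ROOT <- A <- B with all annotations under B: IC(A) = IC(ROOT) = 0
  f <- tempfile()
  write.table(data.frame(term = c("R", "A", "B"),
                         parent = c("", "R", "A"), domain = "MF"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  dag <- readGODag(f, format = "edge-list")
  ic <- computeIC(dag, c(B = 4), "MF")
  expect_warning(S <- buildSimilarityMatrix(dag, ic, c("R", "A")),
                 "unnormalized")
  expect_equal(max(S), 0)
  expect_false(attr(S, "normalized"))
})

test_that("threshold clustering cuts the average-linkage tree", {
  # all similarities 1: one cluster
  S1 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(clusterTerms(S1, 0.8)), rep(1L, 3),
               ignore_attr = TRUE)
  # two clean blocks at threshold 0.8
  S2 <- rbind(c(1, .95, .1, .1), c(.95, 1, .1, .1),
              c(.1, .1, 1, .95), c(.1, .1, .95, 1))
  dimnames(S2) <- list(letters[1:4], letters[1:4])
  cl <- clusterTerms(S2, 0.8)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["c"]], cl[["d"]])
  expect_false(cl[["a"]] == cl[["c"]])
  # threshold 0 merges everything
  expect_equal(length(unique(clusterTerms(S2, 0))), 1L)
  # raising the threshold never decreases the cluster count
  ns <- vapply(c(0, .2, .5, .8, .9, .99), function(th)
    length(unique(clusterTerms(S2, th))), numeric(1))
  expect_true(all(diff(ns) >= 0))
  # labels are contiguous positive integers
  expect_equal(sort(unique(unname(cl))), seq_along(unique(cl)))
})

test_that("minimal subgraph is the ancestor closure with induced edges", {
  fx <- semFixture()
  # single term at depth 2: path of 3 nodes up to the root
  g1 <- minimalSubgraph(fx$dag, "GO:B")
  expect_setequal(igraph::V(g1)$name, c("GO:B", "GO:A", "GO:ROOT"))
  expect_equal(igraph::ecount(g1), 2)
  # two siblings share ancestors without duplication
  g2 <- minimalSubgraph(fx$dag, c("GO:B", "GO:D"))
  expect_setequal(igraph::V(g2)$name,
                  c("GO:B", "GO:D", "GO:A", "GO:ROOT"))
  # transitive-closure oracle on a random toy DAG
  toy <- makeToyDag(12, seed = 31L)
  picks <- toy$terms$id[c(5, 9, 12)]
  gg <- minimalSubgraph(toy$dag, picks)
  childrenOf <- split(toy$edges$child, toy$edges$parent)
  parentsOf <- split(toy$edges$parent, toy$edges$child)
  closure <- unique(unlist(lapply(picks, function(t) {
    seen <- t; frontier <- t
    while (length(frontier)) {
      nxt <- setdiff(unlist(parentsOf[frontier]), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    seen
  })))
  expect_setequal(igraph::V(gg)$name, closure)
  # unknown term dropped with warning
  expect_warning(g3 <- minimalSubgraph(fx$dag, c("GO:B", "GO:NOPE")),
                 "not in DAG")
  expect_setequal(igraph::V(g3)$name, c("GO:B", "GO:A", "GO:ROOT"))
})

test_that("DOT output is structurally valid with per-cluster colors", {
  fx <- semFixture()
  g <- minimalSubgraph(fx$dag, c("GO:B", "GO:C", "GO:D"))
  clusters <- c(`GO:B` = 1L, `GO:D` = 1L, `GO:C` = 2L)
  dot <- emitDot(g, clusters)
  lines <- strsplit(dot, "\n")[[1]]
  expect_match(lines[1], "^digraph")
  expect_equal(sum(lines == "}"), 1L)
  # every vertex declared, every edge parent -> child present
  for (v in igraph::V(g)$name)
    expect_true(any(grepl(paste0('"', v, '"'), lines, fixed = TRUE)))
  expect_true(any(grepl('"GO:A" -> "GO:B"', lines, fixed = TRUE)))
  # exactly 2 distinct fill colors among significant nodes
  cols <- regmatches(dot, gregexpr("fillcolor=\"[^\"]+\"", dot))[[1]]
  expect_equal(length(unique(cols)), 2L)
  # ancestor-only nodes are uncolored
  expect_false(grepl('"GO:ROOT" \\[style="rounded,filled"', dot))
  # a missing cluster label is a contract error
  expect_error(emitDot(g, clusters[-1]), "no cluster label")
})
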