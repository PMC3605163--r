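mkAnno <- function(probesets, goSets, symbols = NULL) {
  df <- data.frame(probeset_id = probesets,
                   gene_symbol = symbols %||% toupper(probesets),
                   entrez_id = NA_character_, genbank_id = NA_character_,
                   stringsAsFactors = FALSE)
  df$go_ids <- goSets
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("term2probeset inverts the annotation and respects the domain", {
  dag <- tinyDag()
  anno <- mkAnno(c("p1", "p2"), list("GO:A", c("GO:A", "GO:B")))
  map <- buildTermProbesetMap(anno, dag, domain = "MF")
  expect_equal(termToProbesets(map),
               list(`GO:A` = c("p1", "p2"), `GO:B` = "p2"))
  expect_equal(probesetToTerms(map),
               list(p1 = "GO:A", p2 = c("GO:A", "GO:B")))

  # term from another domain is excluded
  f <- tempfile()
  write.table(data.frame(term = c("GO:ROOT", "GO:A", "BPROOT", "BP1"),
                         parent = c("", "GO:ROOT", "", "BPROOT"),
                         domain = c("MF", "MF", "BP", "BP")),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  dag2 <- readGODag(f, format = "edge-list")
  anno2 <- mkAnno("p1", list(c("GO:A", "BP1")))
  mapMF <- buildTermProbesetMap(anno2, dag2, domain = "MF")
  expect_named(termToProbesets(mapMF), "GO:A")
})

test_that("propagation attaches annotations to all ancestors", {
  dag <- tinyDag()  # B is_a A is_a ROOT; D is_a A; C is_a ROOT
  anno <- mkAnno(c("p1", "p2"), list("GO:A", c("GO:A", "GO:B")))
  map <- buildTermProbesetMap(anno, dag, domain = "MF", propagate = TRUE)
  fwd <- termToProbesets(map)
  # brute-force ancestor closure oracle over the tiny DAG
  parents <- list(`GO:A` = "GO:ROOT", `GO:B` = c("GO:A"),
                  `GO:C` = "GO:ROOT", `GO:D` = "GO:A",
                  `GO:ROOT` = character())
  closure <- function(t) {
    out <- t
    repeat {
      nxt <- unique(c(out, unlist(parents[out])))
      if (length(nxt) == length(out)) return(out)
      out <- nxt
    }
  }
  expected <- list()
  for (i in seq_len(2)) {
    for (t in unlist(lapply(anno$go_ids[[i]], closure)))
      expected[[t]] <- sort(unique(c(expected[[t]], anno$probeset_id[i])))
  }
  expect_equal(fwd[sort(names(expected))], expected[sort(names(expected))])
  # true-path rule: parent's set contains every child's set
  expect_true(all(fwd$`GO:B` %in% fwd$`GO:A`))
  expect_true(all(fwd$`GO:A` %in% fwd$`GO:ROOT`))
})

test_that("annotations to unknown terms are dropped, not fatal", {
  dag <- tinyDag()
  anno <- mkAnno("p1", list(c("GO:A", "GO:NOPE")))
  expect_message(map <- buildTermProbesetMap(anno, dag, domain = "MF"),
                 "dropped")
  expect_named(termToProbesets(map), "GO:A")
})

test_that("map restriction to expression probesets drops empty terms", {
  dag <- tinyDag()
  anno <- mkAnno(c("p1", "p2"), list("GO:A", "GO:B"))
  map <- buildTermProbesetMap(anno, dag, domain = "MF", probesets = "p1")
  expect_named(termToProbesets(map), "GO:A")
})

test_that("inversion is an exact identity on random maps", {
  set.seed(42)
  for (rep in 1:5) {
    fwd <- lapply(setNames(1:8, paste0("T", 1:8)), function(i)
      sort(sample(paste0("p", 1:20), sample(1:6, 1))))
    rev <- GOwise:::invertMap(fwd)
    back <- GOwise:::invertMap(rev)
    expect_equal(back[sort(names(fwd))],
                 lapply(fwd, sort)[sort(names(fwd))])
  }
})

test_that("gene symbol resolution follows approved > previous > alias", {
  hgnc <- data.frame(
    approved_symbol = c("AKT1", "TP53", "MYC"),
    status = "approved", stringsAsFactors = FALSE)
  hgnc$previous_symbols <- list("AKT", character(), "MYCC")
  hgnc$aliases <- list("PKB", "P53", "PKB")  # PKB ambiguous
  anno <- mkAnno(paste0("p", 1:4), rep(list(character()), 4),
                 symbols = c("TP53", "AKT", "PKB", "ZZZ9"))
  expect_warning(p2g <- buildProbesetToGene(anno, hgnc), "PKB")
  m <- geneMap(p2g)
  expect_equal(m$status,
               c("approved", "previous-resolved", "unresolved",
                 "unresolved"))
  expect_equal(m$resolved_symbol[1:2], c("TP53", "AKT1"))
  expect_equal(m$resolved_symbol[3], "PKB")  # platform symbol kept

  # resolution is independent of table row order
  hgnc2 <- hgnc[c(3, 1, 2), ]
  expect_warning(p2g2 <- buildProbesetToGene(anno, hgnc2), "PKB")
  expect_equal(geneMap(p2g2), geneMap(p2g))
})

test_that("unique alias resolves; withdrawn records are ignored", {
  hgnc <- data.frame(
    approved_symbol = c("BRCA1", "OLDNAME"),
    status = c("approved", "withdrawn"), stringsAsFactors = FALSE)
  hgnc$previous_symbols <- list(character(), character())
  hgnc$aliases <- list("RNF53", "RNF53")
  anno <- mkAnno("p1", list(character()), symbols = "RNF53")
  p2g <- buildProbesetToGene(anno, hgnc)
  expect_equal(geneMap(p2g)$status, "alias-resolved")
  expect_equal(geneMap(p2g)$resolved_symbol, "BRCA1")
})
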