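#' @import methods
#' @importFrom stats median sd rnorm runif as.dist hclust cutree setNames
#' @importFrom utils head
NULL

setOldClass("igraph")

#' Gene Ontology DAG
#'
#' Holds the directed acyclic graph of GO terms for one or more domains
#' (molecular function \code{MF}, biological process \code{BP}, cellular
#' component \code{CC}).  Edges point from child to parent and carry only
#' \code{is_a} relations by default.  Obsolete terms are excluded at load
#' time.
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{domain} (one row per term).
#' @slot graph igraph object; vertices named by term id, directed edges
#'   child -> parent.
#' @slot roots named character vector, domain -> root term id.
#'
#' @seealso [readGODag()], [goAncestors()], [goDescendants()]
#' @export
setClass("GODag",
  representation(terms = "data.frame", graph = "igraph", roots = "character"))

setValidity("GODag", function(object) {
  msg <- character()
  tm <- object@terms
  if (!all(c("id", "name", "domain") %in% names(tm)))
    msg <- c(msg, "terms must have columns id, name, domain")
  if (anyDuplicated(tm$id))
    msg <- c(msg, "duplicate term ids")
  if (!all(tm$domain %in% c("MF", "BP", "CC")))
    msg <- c(msg, "unknown GO domain in terms")
  if (!igraph::is_dag(object@graph))
    msg <- c(msg, "GO graph contains a cycle")
  # every edge must stay within one domain
  el <- igraph::as_edgelist(object@graph)
  if (nrow(el) > 0L) {
    dom <- setNames(tm$domain, tm$id)
    if (any(dom[el[, 1L]] != dom[el[, 2L]]))
      msg <- c(msg, "is_a edge crossing GO domains")
  }
  # every non-root term has >= 1 parent within its domain
  outdeg <- igraph::degree(object@graph, mode = "out")
  orphan <- setdiff(names(outdeg)[outdeg == 0L], object@roots)
  if (length(orphan))
    msg <- c(msg, paste0("non-root terms without parents: ",
                         paste(head(orphan, 5L), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Bidirectional GO term / probeset map
#'
#' The derived "term2probeset" mapping restricted to one GO domain and to
#' probesets present in the expression matrix.  The two slot maps are exact
#' inverses of each other.
#'
#' @slot term2probeset named list: term id -> character vector of probesets.
#' @slot probeset2term named list: probeset id -> character vector of terms.
#' @slot domain single GO domain ("MF", "BP" or "CC").
#'
#' @seealso [buildTermProbesetMap()]
#' @export
setClass("TermProbesetMap",
  representation(term2probeset = "list", probeset2term = "list",
                 domain = "character"))

setValidity("TermProbesetMap", function(object) {
  msg <- character()
  if (length(object@domain) != 1L || !object@domain %in% c("MF", "BP", "CC"))
    msg <- c(msg, "domain must be one of MF, BP, CC")
  fwd <- object@term2probeset
  rev <- object@probeset2term
  # inversion identity
  pairsF <- if (length(fwd))
    paste(rep(names(fwd), lengths(fwd)), unlist(fwd, use.names = FALSE))
  else character()
  pairsR <- if (length(rev))
    paste(unlist(rev, use.names = FALSE), rep(names(rev), lengths(rev)))
  else character()
  if (!setequal(pairsF, pairsR))
    msg <- c(msg, "term2probeset and probeset2term are not exact inverses")
  if (any(lengths(fwd) == 0L))
    msg <- c(msg, "terms mapped to zero probesets must be dropped")
  if (length(msg)) msg else TRUE
})

#' HGNC-verified probeset to gene map
#'
#' The derived "probeset2gene" mapping: each platform gene symbol is
#' resolved against a gene-naming table (approved symbols first, then
#' previous symbols, then aliases).
#'
#' @slot map data.frame with columns \code{probeset_id},
#'   \code{platform_symbol}, \code{resolved_symbol}, \code{status}
#'   (approved / previous-resolved / alias-resolved / unresolved),
#'   \code{entrez_id}, \code{genbank_id}.
#'
#' @seealso [buildProbesetToGene()]
#' @export
setClass("ProbesetGeneMap", representation(map = "data.frame"))

setValidity("ProbesetGeneMap", function(object) {
  need <- c("probeset_id", "platform_symbol", "resolved_symbol", "status",
            "entrez_id", "genbank_id")
  if (!all(need %in% names(object@map)))
    return(paste("map must have columns:", paste(need, collapse = ", ")))
  ok <- c("approved", "previous-resolved", "alias-resolved", "unresolved")
  if (!all(object@map$status %in% ok))
    return("invalid resolution status")
  TRUE
})

#' Masked per-term expression subset
#'
#' The P_X x N submatrix of the expression matrix holding the rows of the
#' probesets annotated to one GO term, with the learning technique the
#' subset is routed to.
#'
#' @slot termId GO term id.
#' @slot values numeric matrix, probesets x samples; rows are exact copies
#'   of the source expression rows.
#' @slot technique "L1L2FS" or "RLS".
#' @export
setClass("TermSubset",
  representation(termId = "character", values = "matrix",
                 technique = "character"))

setValidity("TermSubset", function(object) {
  msg <- character()
  if (nrow(object@values) < 1L) msg <- c(msg, "subset must have >= 1 row")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    msg <- c(msg, "values must carry probeset and sample dimnames")
  if (!object@technique %in% c("L1L2FS", "RLS", ""))
    msg <- c(msg, "technique must be L1L2FS or RLS")
  if (length(msg)) msg else TRUE
})

#' Solver and cross-validation configuration
#'
#' @slot muValues correlation (squared-l2) penalties mu >= 0; larger mu
#'   draws more correlated variables into the selected set.
#' @slot l1Grid explicit l1 penalty grid; empty means a geometric grid of
#'   \code{nL1} values from \code{l1MinRatio * l1_max} to \code{l1_max} is
#'   built per outer training fold, where l1_max is the smallest penalty
#'   shrinking all weights to zero.
#' @slot nL1,l1MinRatio automatic-grid shape parameters.
#' @slot innerK,outerK fold counts of the nested cross-validation loops.
#' @slot tol KKT/subgradient tolerance of the l1l2 solver.
#' @slot maxIter iteration cap of the l1l2 solver.
#' @slot seed master RNG seed; every task derives its own stream from it.
#' @slot standardize center/scale columns with outer-training statistics.
#' @export
setClass("SolverConfig",
  representation(muValues = "numeric", l1Grid = "numeric", nL1 = "integer",
                 l1MinRatio = "numeric", innerK = "integer",
                 outerK = "integer", tol = "numeric", maxIter = "integer",
                 seed = "integer", standardize = "logical"))

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (length(object@muValues) < 1L || any(object@muValues < 0))
    msg <- c(msg, "muValues must be non-empty and >= 0")
  if (any(object@l1Grid < 0)) msg <- c(msg, "l1Grid values must be >= 0")
  if (object@innerK < 2L || object@outerK < 2L)
    msg <- c(msg, "innerK and outerK must be >= 2")
  if (object@tol <= 0 || object@maxIter < 1L)
    msg <- c(msg, "tol must be > 0 and maxIter >= 1")
  if (length(msg)) msg else TRUE
})

#' Per-term selection result
#'
#' Output of the knowledge-discovery step on one GO-term subset: per-mu
#' split results (outer-fold test/train errors, confusion counts, selected
#' variables), selection frequencies and summary statistics.  RLS-routed
#' subsets carry a single pseudo-mu entry keyed \code{"RLS"}.
#'
#' @slot termId GO term id.
#' @slot technique "L1L2FS" or "RLS".
#' @slot perMu named list (one entry per mu key, e.g. "mu1") of lists with
#'   elements \code{mu}, \code{splits}, \code{frequencies},
#'   \code{mean_test_error}, \code{sd_test_error}, \code{median_test_error},
#'   \code{mean_train_error}, \code{sd_train_error}.
#' @slot probesetIds variables of the subset (length P_X).
#' @slot outerK number of outer folds.
#' @slot nSamples number of samples.
#' @export
setClass("SelectionResult",
  representation(termId = "character", technique = "character",
                 perMu = "list", probesetIds = "character",
                 outerK = "integer", nSamples = "integer"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (!object@technique %in% c("L1L2FS", "RLS"))
    msg <- c(msg, "technique must be L1L2FS or RLS")
  for (entry in object@perMu) {
    fr <- entry$frequencies
    if (any(fr < 0L) || any(fr > object@outerK))
      msg <- c(msg, "frequencies must lie in [0, outerK]")
    if (length(entry$splits) != object@outerK)
      msg <- c(msg, "one SplitResult per outer fold required")
  }
  if (length(msg)) msg else TRUE
})

#' Directory-backed relational store
#'
#' Queryable store of the raw tables (GEDM, ANNO, HGNC, LABELS) and derived
#' tables (term2probeset, probeset2gene).  Tables live in memory as
#' data.tables and are persisted as one TSV per table under \code{dir}.
#'
#' @slot dir directory the tables are persisted to.
#' @slot tables environment mapping table name -> data.table.
#' @export
setClass("RelationalStore",
  representation(dir = "character", tables = "environment"))

# ---- show methods ---------------------------------------------------------

setMethod("show", "GODag", function(object) {
  cat("GODag with", nrow(object@terms), "terms,",
      igraph::ecount(object@graph), "is_a edges\n")
  for (d in names(object@roots))
    cat("  ", d, " root: ", object@roots[[d]], " (",
        sum(object@terms$domain == d), " terms)\n", sep = "")
})

setMethod("show", "TermProbesetMap", function(object) {
  cat("TermProbesetMap [", object@domain, "]: ",
      length(object@term2probeset), " terms <-> ",
      length(object@probeset2term), " probesets\n", sep = "")
})

setMethod("show", "ProbesetGeneMap", function(object) {
  cat("ProbesetGeneMap:", nrow(object@map), "probesets\n")
  print(table(object@map$status))
})

setMethod("show", "TermSubset", function(object) {
  cat("TermSubset ", object@termId, ": ", nrow(object@values), " x ",
      ncol(object@values), ", technique ",
      if (nzchar(object@technique)) object@technique else "<unrouted>",
      "\n", sep = "")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult ", object@termId, " (", object@technique, "), P_X=",
      length(object@probesetIds), ", outerK=", object@outerK, "\n", sep = "")
  for (k in names(object@perMu))
    cat(sprintf("  %s: mean test error %.3f (sd %.3f)\n", k,
                object@perMu[[k]]$mean_test_error,
                object@perMu[[k]]$sd_test_error))
})

setMethod("show", "RelationalStore", function(object) {
  nm <- ls(object@tables)
  cat("RelationalStore at", object@dir, "with tables:",
      paste(nm, collapse = ", "), "\n")
})
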