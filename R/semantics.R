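# Semantic interpretation of significant terms: information content,
# Resnik similarity, threshold clustering, minimal subgraph, DOT emission.

#' Annotation corpus from a term/probeset map
#'
#' By default the information-content corpus is the term2probeset map
#' itself: each direct probeset annotation of a term counts once.  An
#' external association table (data.frame with columns term_id, count or
#' one row per association) can be supplied instead.
#'
#' @param map a [TermProbesetMap-class]
#' @return named numeric vector of direct annotation counts per term
#' @export
annotationCorpus <- function(map) {
  vapply(termToProbesets(map), length, numeric(1))
}

#' Information content of GO terms
#'
#' IC(t) = -log( annotations subsumed by t / annotations subsumed by the
#' domain root ), where "subsumed" sums the direct corpus counts over the
#' term and all its descendants.  The root has IC 0; IC never decreases
#' from parent to child.  Natural log (nats); the base cancels after
#' normalization.  Terms subsuming zero annotations have undefined IC
#' (NA) and are excluded from similarity with a warning.
#'
#' @param dag a [GODag-class]
#' @param corpus named numeric vector of direct annotation counts
#' @param domain GO domain
#' @return named numeric vector (ICMap) over the domain's terms
#' @export
computeIC <- function(dag, corpus, domain = c("MF", "BP", "CC")) {
  domain <- match.arg(domain)
  terms <- goTerms(dag)
  ids <- terms$id[terms$domain == domain]
  cnt <- setNames(numeric(length(ids)), ids)
  known <- intersect(names(corpus), ids)
  cnt[known] <- as.numeric(corpus[known])
  subsumed <- vapply(ids, function(t)
    sum(cnt[goDescendants(dag, t, includeSelf = TRUE)]), numeric(1))
  rootTotal <- subsumed[[goRoots(dag)[[domain]]]]
  if (rootTotal <= 0)
    stop("root of domain ", domain, " subsumes no annotations")
  ic <- -log(subsumed / rootTotal)
  undef <- !is.finite(ic)
  if (any(undef)) {
    warning(sum(undef), " term(s) subsume zero annotations; IC undefined",
            call. = FALSE)
    ic[undef] <- NA_real_
  }
  ic
}

#' Resnik semantic similarity of two terms
#'
#' The information content of the most-informative common ancestor (the
#' terms themselves count as their own ancestors).  Within a domain the
#' root is always a common ancestor, so the similarity of unrelated terms
#' is IC(root) = 0.
#'
#' @param dag a [GODag-class]
#' @param ic ICMap from [computeIC()]
#' @param t1,t2 term ids within one domain with defined IC
#' @return non-negative similarity (nats)
#' @export
resnikSimilarity <- function(dag, ic, t1, t2) {
  a1 <- goAncestors(dag, t1, includeSelf = TRUE)
  a2 <- goAncestors(dag, t2, includeSelf = TRUE)
  common <- intersect(a1, a2)
  common <- common[!is.na(ic[common])]
  if (!length(common))
    stop("no common ancestor with defined IC for ", t1, " and ", t2,
         " (malformed DAG?)")
  max(ic[common])
}

#' Normalized Resnik similarity matrix
#'
#' Pairwise Resnik similarities of the given terms (diagonal = each term's
#' own IC), divided by the maximum observed entry so the maximum is 1.
#' Diagonal entries participate in the normalization.  Terms with
#' undefined IC are excluded with a warning; an all-zero raw matrix is
#' returned unnormalized with a warning.
#'
#' @param dag a [GODag-class]
#' @param ic ICMap from [computeIC()]
#' @param terms >= 2 term ids
#' @return symmetric similarity matrix with attribute \code{"normalized"}
#' @export
buildSimilarityMatrix <- function(dag, ic, terms) {
  usable <- terms[!is.na(ic[terms])]
  dropped <- setdiff(terms, usable)
  if (length(dropped))
    warning("term(s) with undefined IC excluded from similarity: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (length(usable) < 2L)
    stop("need >= 2 terms with defined IC for a similarity matrix")
  k <- length(usable)
  S <- matrix(0, k, k, dimnames = list(usable, usable))
  for (i in seq_len(k)) for (j in i:k) {
    S[i, j] <- S[j, i] <- resnikSimilarity(dag, ic, usable[i], usable[j])
  }
  m <- max(S)
  if (m == 0) {
    warning("all Resnik similarities are zero; matrix left unnormalized",
            call. = FALSE)
    attr(S, "normalized") <- FALSE
    return(S)
  }
  S <- S / m
  attr(S, "normalized") <- TRUE
  S
}

#' Cluster significant terms by semantic similarity
#'
#' Agglomerative hierarchical clustering on the distance 1 - normalized
#' similarity, cut into flat clusters at distance 1 - semanticThreshold
#' (default threshold 0.8).  Cluster labels are contiguous positive
#' integers in order of first appearance.
#'
#' @param sim normalized similarity matrix from [buildSimilarityMatrix()]
#' @param semanticThreshold similarity threshold in [0, 1]
#' @param linkage "average" (default), "single" or "complete"
#' @return named integer vector of cluster labels with attribute
#'   \code{"threshold"}
#' @export
clusterTerms <- function(sim, semanticThreshold = 0.8,
                         linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(semanticThreshold >= 0, semanticThreshold <= 1)
  d <- as.dist(1 - sim)
  hc <- hclust(d, method = linkage)
  raw <- cutree(hc, h = 1 - semanticThreshold)
  labels <- setNames(match(raw, unique(raw)), names(raw))
  attr(labels, "threshold") <- semanticThreshold
  labels
}

#' Minimal GO subgraph over a term set
#'
#' Node set = the terms plus all their ancestors up to the domain root;
#' edge set = the induced is_a edges.  Terms absent from the DAG are
#' dropped with a warning.
#'
#' @param dag a [GODag-class]
#' @param terms term ids within one domain
#' @return igraph subgraph (edges child -> parent) with vertex attribute
#'   \code{significant} marking the query terms
#' @export
minimalSubgraph <- function(dag, terms) {
  known <- intersect(terms, goTerms(dag)$id)
  missing <- setdiff(terms, known)
  if (length(missing))
    warning("term(s) not in DAG dropped from subgraph: ",
            paste(missing, collapse = ", "), call. = FALSE)
  nodes <- union(known, goAncestors(dag, known, includeSelf = TRUE))
  g <- igraph::induced_subgraph(dag@graph, nodes)
  igraph::V(g)$significant <- igraph::V(g)$name %in% known
  g
}

# Fixed deterministic 12-color palette; cluster index cycles through it.
clusterPalette <- c("#a6cee3", "#1f78b4", "#b2df8a", "#33a02c", "#fb9a99",
                    "#e31a1c", "#fdbf6f", "#ff7f00", "#cab2d6", "#6a3d9a",
                    "#ffff99", "#b15928")

#' Emit the minimal subgraph as DOT text
#'
#' Significant terms are filled with a per-cluster color from a fixed
#' 12-color cycle; ancestor-only nodes stay uncolored; edges run parent ->
#' child (the biological reading direction).  Output ordering is
#' deterministic.
#'
#' @param subgraph igraph from [minimalSubgraph()]
#' @param clusters named cluster labels from [clusterTerms()] covering
#'   every significant node
#' @return DOT source as a single character string
#' @export
emitDot <- function(subgraph, clusters) {
  nodes <- sort(igraph::V(subgraph)$name)
  sig <- igraph::V(subgraph)$name[igraph::V(subgraph)$significant]
  lines <- c("digraph go_minimal_subgraph {",
             "  node [shape=box, style=rounded];")
  for (v in nodes) {
    if (v %in% sig) {
      if (!v %in% names(clusters))
        stop("significant term ", v, " has no cluster label")
      col <- clusterPalette[(clusters[[v]] - 1L) %% 12L + 1L]
      lines <- c(lines, sprintf(
        "  \"%s\" [style=\"rounded,filled\", fillcolor=\"%s\"];", v, col))
    } else {
      lines <- c(lines, sprintf("  \"%s\";", v))
    }
  }
  el <- igraph::as_edgelist(subgraph)
  if (nrow(el)) {
    eg <- sprintf("  \"%s\" -> \"%s\";", el[, 2L], el[, 1L])  # parent->child
    lines <- c(lines, sort(eg))
  }
  paste(c(lines, "}"), collapse = "\n")
}
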