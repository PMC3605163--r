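# Local data integration: the derived term2probeset and probeset2gene maps.

#' Build the bidirectional GO term / probeset map
#'
#' Inverts the platform annotation (probeset -> GO terms) into the derived
#' term2probeset mapping, restricted to one GO domain and (optionally) to
#' the probesets actually present in the expression matrix.  Annotations
#' referencing terms absent from the DAG are logged and dropped, never
#' fatal.  With \code{propagate = TRUE} each annotation is additionally
#' attached to all DAG ancestors of its term within the domain (true-path
#' rule); the default is direct annotations only, i.e. the map mirrors the
#' platform annotation as stated.
#'
#' @param anno annotation data.frame from [readAnnotations()]
#' @param dag a [GODag-class]
#' @param domain GO domain ("MF", "BP" or "CC")
#' @param propagate apply the true-path rule (default FALSE)
#' @param probesets restrict to these probeset ids (e.g.
#'   \code{rownames(se)}); NULL keeps all annotated probesets
#' @return a [TermProbesetMap-class]; terms with zero surviving probesets
#'   are dropped
#' @export
buildTermProbesetMap <- function(anno, dag, domain = c("MF", "BP", "CC"),
                                 propagate = FALSE, probesets = NULL) {
  domain <- match.arg(domain)
  terms <- goTerms(dag)
  domainTerms <- terms$id[terms$domain == domain]
  keep <- if (is.null(probesets)) anno$probeset_id
          else intersect(anno$probeset_id, probesets)
  fwd <- new.env(parent = emptyenv())
  nDropped <- 0L
  for (i in seq_len(nrow(anno))) {
    ps <- anno$probeset_id[i]
    if (!ps %in% keep) next
    ids <- anno$go_ids[[i]]
    unknown <- setdiff(ids, terms$id)
    nDropped <- nDropped + length(unknown)
    ids <- intersect(ids, domainTerms)
    if (propagate && length(ids))
      ids <- intersect(goAncestors(dag, ids, includeSelf = TRUE),
                       domainTerms)
    for (t in ids)
      assign(t, c(if (exists(t, envir = fwd)) get(t, envir = fwd), ps),
             envir = fwd)
  }
  if (nDropped > 0L)
    gowiseLog(nDropped, " annotation(s) referenced terms absent from the ",
              "DAG and were dropped", phase = "integration")
  fwdList <- lapply(sort(ls(fwd)), function(t)
    sort(unique(get(t, envir = fwd))))
  names(fwdList) <- sort(ls(fwd))
  fwdList <- fwdList[lengths(fwdList) > 0L]
  revList <- invertMap(fwdList)
  obj <- new("TermProbesetMap", term2probeset = fwdList,
             probeset2term = revList, domain = domain)
  validObject(obj)
  obj
}

# Invert a named list of character vectors (sorted, deterministic).
invertMap <- function(fwd) {
  if (!length(fwd)) return(list())
  long <- data.frame(key = rep(names(fwd), lengths(fwd)),
                     val = unlist(fwd, use.names = FALSE),
                     stringsAsFactors = FALSE)
  out <- split(long$key, long$val)
  out <- lapply(out, function(x) sort(unique(x)))
  out[sort(names(out))]
}

#' Build the HGNC-verified probeset to gene map
#'
#' Resolves each platform gene symbol against the gene-naming table using
#' the resolution order approved symbol > previous symbol > alias.  A
#' symbol matching the previous symbols or aliases of two or more approved
#' records is ambiguous and left unresolved with a warning; unresolved
#' records keep the platform symbol.  Resolution is deterministic and
#' independent of table row order.
#'
#' @param anno annotation data.frame from [readAnnotations()]
#' @param hgnc gene-name data.frame from [readGeneNames()]
#' @return a [ProbesetGeneMap-class]
#' @export
buildProbesetToGene <- function(anno, hgnc) {
  active <- hgnc[hgnc$status != "withdrawn", , drop = FALSE]
  approved <- active$approved_symbol
  prevIdx <- data.frame(
    sym = unlist(active$previous_symbols, use.names = FALSE),
    app = rep(approved, lengths(active$previous_symbols)),
    stringsAsFactors = FALSE)
  aliasIdx <- data.frame(
    sym = unlist(active$aliases, use.names = FALSE),
    app = rep(approved, lengths(active$aliases)),
    stringsAsFactors = FALSE)
  resolveOne <- function(sym) {
    if (is.na(sym) || !nzchar(sym))
      return(c(sym = NA_character_, status = "unresolved"))
    if (sym %in% approved)
      return(c(sym = sym, status = "approved"))
    hits <- sort(unique(prevIdx$app[prevIdx$sym == sym]))
    if (length(hits) == 1L)
      return(c(sym = hits, status = "previous-resolved"))
    if (length(hits) > 1L) {
      warning("symbol '", sym, "' is a previous symbol of ",
              length(hits), " approved records; left unresolved",
              call. = FALSE)
      return(c(sym = sym, status = "unresolved"))
    }
    hits <- sort(unique(aliasIdx$app[aliasIdx$sym == sym]))
    if (length(hits) == 1L)
      return(c(sym = hits, status = "alias-resolved"))
    if (length(hits) > 1L)
      warning("alias '", sym, "' maps to ", length(hits),
              " approved symbols; left unresolved", call. = FALSE)
    c(sym = sym, status = "unresolved")
  }
  res <- vapply(anno$gene_symbol, resolveOne, character(2))
  map <- data.frame(probeset_id = anno$probeset_id,
                    platform_symbol = anno$gene_symbol,
                    resolved_symbol = unname(res["sym", ]),
                    status = unname(res["status", ]),
                    entrez_id = anno$entrez_id,
                    genbank_id = anno$genbank_id,
                    stringsAsFactors = FALSE)
  obj <- new("ProbesetGeneMap", map = map)
  validObject(obj)
  obj
}

#' Persist derived maps in the relational store
#'
#' Writes the term2probeset map as a two-column long table and the
#' probeset2gene map as-is, under the derived-table names.
#'
#' @param store a [RelationalStore-class]
#' @param tpm a [TermProbesetMap-class]
#' @param p2g a [ProbesetGeneMap-class]
#' @return the store, invisibly
#' @export
storeDerivedTables <- function(store, tpm, p2g) {
  fwd <- termToProbesets(tpm)
  long <- data.frame(term_id = rep(names(fwd), lengths(fwd)),
                     probeset_id = unlist(fwd, use.names = FALSE),
                     stringsAsFactors = FALSE)
  storeTable(store, "term2probeset", long)
  storeTable(store, "probeset2gene", geneMap(p2g))
  invisible(store)
}
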