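# Ingestion of the external inputs: expression matrix, labels, platform
# annotations, gene-naming table and GO graph.

#' Read a gene expression data matrix (GEDM)
#'
#' Reads a delimiter-separated expression matrix of P probeset rows by
#' N + 1 columns (first column = probeset ids, header row = sample ids)
#' into a [SummarizedExperiment::SummarizedExperiment] with a single
#' \code{exprs} assay.
#'
#' @param path file path.
#' @param sep field delimiter (default tab); never sniffed.
#' @param impute if TRUE, missing values are imputed with the row median;
#'   by default any missing value is rejected.
#' @return SummarizedExperiment, rownames = probeset ids, colnames =
#'   sample ids.
#' @details Ragged rows, duplicate probeset ids and non-numeric cells are
#'   hard errors reporting the offending line / coordinates.
#' @export
readGEDM <- function(path, sep = "\t", impute = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("GEDM must have a header plus >= 1 row")
  cells <- strsplit(lines, sep, fixed = TRUE)
  width <- length(cells[[1L]])
  bad <- which(lengths(cells) != width)
  if (length(bad))
    stop("ragged GEDM: line ", bad[1L], " has ", length(cells[[bad[1L]]]),
         " fields, expected ", width)
  header <- cells[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in GEDM header")
  body <- cells[-1L]
  probesets <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(probesets))
    stop("duplicate probeset id in GEDM: ",
         probesets[duplicated(probesets)][1L])
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(probesets, samples))
  for (i in seq_along(body)) {
    raw <- body[[i]][-1L]
    num <- suppressWarnings(as.numeric(raw))
    miss <- which(is.na(num) & nzchar(raw))
    if (length(miss))
      stop("non-numeric cell at GEDM line ", i + 1L, ", column ",
           miss[1L] + 1L, ": '", raw[miss[1L]], "'")
    vals[i, ] <- num
  }
  if (anyNA(vals)) {
    if (!impute)
      stop("missing expression values present (set impute=TRUE to use ",
           "row-median imputation)")
    for (i in seq_len(nrow(vals))) {
      na <- is.na(vals[i, ])
      if (all(na)) stop("probeset ", probesets[i], " has no observed values")
      vals[i, na] <- median(vals[i, !na])
    }
  }
  if (ncol(vals) < 2L) stop("GEDM must contain >= 2 samples")
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = vals))
}

#' Read two-class sample labels
#'
#' @param path TSV with columns \code{sample} and \code{label}.
#' @param classMap named numeric vector mapping each raw label to -1 or +1
#'   (explicit by design: never inferred from sort order).
#' @param sep field delimiter.
#' @return named numeric vector of -1/+1 labels, names = sample ids.
#' @export
readLabels <- function(path, classMap, sep = "\t") {
  stopifnot(file.exists(path))
  df <- readTsv(path, sep = sep, colClasses = "character")
  if (!all(c("sample", "label") %in% names(df)))
    stop("labels file must have columns 'sample' and 'label'")
  raw <- unique(df$label)
  if (length(raw) != 2L)
    stop("expected exactly 2 raw labels, found ", length(raw), ": ",
         paste(raw, collapse = ", "))
  if (!all(raw %in% names(classMap)))
    stop("unmapped raw label(s): ",
         paste(setdiff(raw, names(classMap)), collapse = ", "))
  if (!setequal(unname(classMap[raw]), c(-1, 1)))
    stop("classMap must send the two raw labels to -1 and +1")
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in labels file")
  y <- setNames(as.numeric(classMap[df$label]), df$sample)
  if (min(table(y)) < 2L)
    stop("each class must contain >= 2 samples")
  y
}

#' Attach labels to an expression matrix
#'
#' @param se SummarizedExperiment from [readGEDM()].
#' @param labels named -1/+1 vector from [readLabels()].
#' @return the SummarizedExperiment with a \code{label} colData column,
#'   restricted to the labeled samples (original column order kept).
#' @export
attachLabels <- function(se, labels) {
  common <- intersect(colnames(se), names(labels))
  if (length(common) < 4L)
    stop("fewer than 4 labeled samples match the expression matrix")
  se <- se[, common]
  se$label <- unname(labels[common])
  if (length(unique(se$label)) != 2L)
    stop("both classes must be present among matched samples")
  se
}

#' Read a platform annotation table
#'
#' @param path DSV file, GEO-GPL style.
#' @param columns named list/vector giving the file's column names for the
#'   roles \code{probeset}, \code{symbol}, \code{go}, and optionally
#'   \code{entrez}, \code{genbank}.
#' @param goSep separator of the multi-valued GO cell (platform dependent;
#'   default ";").
#' @param sep field delimiter.
#' @return data.frame with columns probeset_id, gene_symbol, go_ids
#'   (list column of character vectors), entrez_id, genbank_id.
#' @export
readAnnotations <- function(path,
                            columns = c(probeset = "probeset_id",
                                        symbol = "gene_symbol",
                                        go = "go_terms",
                                        entrez = "entrez_id",
                                        genbank = "genbank_id"),
                            goSep = ";", sep = "\t") {
  stopifnot(file.exists(path))
  df <- readTsv(path, sep = sep, colClasses = "character")
  need <- columns[c("probeset", "symbol", "go")]
  miss <- setdiff(unname(need), names(df))
  if (length(miss))
    stop("annotation file lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df[[columns[["probeset"]]]]))
    stop("duplicate probeset rows in annotation table")
  pick <- function(role) {
    col <- columns[role]
    if (!is.na(col) && col %in% names(df)) df[[col]] else NA_character_
  }
  go <- lapply(df[[columns[["go"]]]], function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character())
    unique(trimws(strsplit(cell, goSep, fixed = TRUE)[[1L]]))
  })
  out <- data.frame(probeset_id = df[[columns[["probeset"]]]],
                    gene_symbol = df[[columns[["symbol"]]]],
                    entrez_id = pick("entrez"),
                    genbank_id = pick("genbank"),
                    stringsAsFactors = FALSE)
  out$go_ids <- go
  out
}

#' Read a gene-naming (HGNC-style) table
#'
#' @param path TSV with columns \code{approved_symbol}, \code{status},
#'   \code{previous_symbols}, \code{aliases} (multi-valued cells separated
#'   by `multiSep`).
#' @param multiSep separator within multi-valued cells.
#' @param sep field delimiter.
#' @return data.frame with list columns \code{previous_symbols} and
#'   \code{aliases}.
#' @export
readGeneNames <- function(path, multiSep = ";", sep = "\t") {
  stopifnot(file.exists(path))
  df <- readTsv(path, sep = sep, colClasses = "character")
  need <- c("approved_symbol", "status", "previous_symbols", "aliases")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene-name table lacks column(s): ", paste(miss, collapse = ", "))
  active <- df$status != "withdrawn"
  if (anyDuplicated(df$approved_symbol[active]))
    stop("duplicate approved symbols among non-withdrawn records")
  splitCell <- function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character())
    unique(trimws(strsplit(cell, multiSep, fixed = TRUE)[[1L]]))
  }
  df$previous_symbols <- lapply(df$previous_symbols, splitCell)
  df$aliases <- lapply(df$aliases, splitCell)
  df
}

# Internal GODag constructor from a term table and child->parent edges.
newGODag <- function(terms, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$id)
  if (!igraph::is_dag(g)) {
    cyc <- tryCatch({
      comp <- igraph::components(g, mode = "strong")
      names(comp$membership)[comp$membership ==
        which(comp$csize > 1L)[1L]]
    }, error = function(e) character())
    stop("GO graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  outdeg <- igraph::degree(g, mode = "out")
  roots <- character()
  for (d in unique(terms$domain)) {
    cand <- intersect(names(outdeg)[outdeg == 0L],
                      terms$id[terms$domain == d])
    if (length(cand) != 1L)
      stop("domain ", d, " must have exactly one root, found ",
           length(cand))
    roots[[d]] <- cand
  }
  new("GODag", terms = terms, graph = g, roots = roots)
}

#' Read a Gene Ontology DAG
#'
#' Supported formats: minimal OBO (term stanzas with id, name, namespace,
#' is_a; obsolete terms skipped) and a plain 3-column edge list
#' (TSV columns \code{term}, \code{parent}, \code{domain}; empty parent
#' marks a root; term names default to the id).
#'
#' @param path file path.
#' @param format "obo" or "edge-list".
#' @return a [GODag-class].
#' @export
readGODag <- function(path, format = c("obo", "edge-list")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "obo") {
    parsed <- parseObo(path)
    terms <- parsed$terms; edges <- parsed$edges
  } else {
    df <- readTsv(path, colClasses = "character")
    need <- c("term", "parent", "domain")
    if (!all(need %in% names(df)))
      stop("edge list must have columns term, parent, domain")
    terms <- unique(data.frame(id = df$term, name = df$term,
                               domain = df$domain, stringsAsFactors = FALSE))
    if (anyDuplicated(terms$id))
      stop("term listed with conflicting domains in edge list")
    hasParent <- !is.na(df$parent) & nzchar(df$parent)
    edges <- data.frame(child = df$term[hasParent],
                        parent = df$parent[hasParent],
                        stringsAsFactors = FALSE)
    unknown <- setdiff(edges$parent, terms$id)
    if (length(unknown))
      stop("edge list references unknown parent term(s): ",
           paste(unknown, collapse = ", "))
  }
  if (nrow(terms) == 0L) stop("no terms parsed from ", path)
  dag <- newGODag(terms, edges)
  validObject(dag)
  dag
}

#' Term table, roots and graph of a GODag
#' @param dag a [GODag-class]
#' @return `goTerms`: data.frame (id, name, domain); `goRoots`: named
#'   character vector domain -> root id.
#' @export
goTerms <- function(dag) dag@terms

#' @rdname goTerms
#' @export
goRoots <- function(dag) dag@roots

#' Ancestor / descendant closure in the GO DAG
#'
#' @param dag a [GODag-class]
#' @param ids term ids
#' @param includeSelf include the query terms themselves
#' @return character vector of term ids (union over `ids`)
#' @export
goAncestors <- function(dag, ids, includeSelf = FALSE) {
  ids <- intersect(ids, dag@terms$id)
  res <- unique(unlist(lapply(ids, function(t)
    names(igraph::subcomponent(dag@graph, t, mode = "out")))))
  if (!includeSelf) res <- setdiff(res, ids)
  res %||% character()
}

#' @rdname goAncestors
#' @export
goDescendants <- function(dag, ids, includeSelf = FALSE) {
  ids <- intersect(ids, dag@terms$id)
  res <- unique(unlist(lapply(ids, function(t)
    names(igraph::subcomponent(dag@graph, t, mode = "in")))))
  if (!includeSelf) res <- setdiff(res, ids)
  res %||% character()
}
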