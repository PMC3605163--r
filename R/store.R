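# Directory-backed relational store for raw and derived tables.
# Contract: a DSV of A columns / B rows loads into a table of A columns /
# B rows; lookups by probeset, sample and gene symbol; persisted as one TSV
# per table so a completed ensemble can be reopened read-only.

#' Create a relational store
#' @param dir directory for persisted tables (created if needed).
#' @return a [RelationalStore-class]
#' @export
createStore <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  new("RelationalStore", dir = dir, tables = new.env(parent = emptyenv()))
}

#' Store a table
#' @param store a [RelationalStore-class]
#' @param name table name (e.g. "GEDM", "ANNO", "HGNC", "LABELS")
#' @param df data.frame to store (row count preserved exactly)
#' @return the store, invisibly
#' @export
storeTable <- function(store, name, df) {
  dt <- data.table::as.data.table(df)
  assign(name, dt, envir = store@tables)
  writeTsv(dt, file.path(store@dir, paste0(name, ".tsv")))
  invisible(store)
}

#' Fetch a whole table
#' @param store a [RelationalStore-class]
#' @param name table name
#' @return data.frame
#' @export
fetchTable <- function(store, name) {
  if (!exists(name, envir = store@tables))
    stop("no table '", name, "' in store")
  as.data.frame(get(name, envir = store@tables))
}

#' List table names
#' @param store a [RelationalStore-class]
#' @return character vector
#' @export
storeTables <- function(store) sort(ls(store@tables))

#' Query a table by key column
#'
#' Returns the matching rows; a missing key yields an empty result, never
#' an error.
#'
#' @param store a [RelationalStore-class]
#' @param name table name
#' @param column key column name
#' @param value key value(s)
#' @return data.frame of matching rows
#' @export
storeQuery <- function(store, name, column, value) {
  dt <- data.table::as.data.table(fetchTable(store, name))
  if (!column %in% names(dt))
    stop("table '", name, "' has no column '", column, "'")
  as.data.frame(dt[dt[[column]] %in% value])
}

#' Reopen a persisted store
#' @param dir directory previously used by [createStore()]
#' @return a [RelationalStore-class] with all persisted tables loaded
#' @export
openStore <- function(dir) {
  store <- createStore(dir)
  for (f in list.files(dir, pattern = "\\.tsv$")) {
    nm <- sub("\\.tsv$", "", f)
    assign(nm, data.table::fread(file.path(dir, f), sep = "\t",
                                 header = TRUE, na.strings = NULL,
                                 showProgress = FALSE),
           envir = store@tables)
  }
  store
}

#' Load the raw input tables into a store
#'
#' Persists the four raw tables GEDM, ANNO, HGNC and LABELS.  Multi-valued
#' cells (GO ids, previous symbols, aliases) are re-joined with ";" for
#' storage; the in-memory readers remain the typed access path.
#'
#' @param store a [RelationalStore-class]
#' @param se labeled expression SummarizedExperiment
#' @param anno annotation data.frame from [readAnnotations()]
#' @param hgnc gene-name data.frame from [readGeneNames()]
#' @return the store, invisibly
#' @export
loadRawTables <- function(store, se, anno, hgnc) {
  vals <- SummarizedExperiment::assay(se, "exprs")
  gedm <- data.frame(probeset_id = rownames(vals), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
  storeTable(store, "GEDM", gedm)
  annoFlat <- data.frame(
    probeset_id = anno$probeset_id, gene_symbol = anno$gene_symbol,
    go_terms = vapply(anno$go_ids, paste, character(1), collapse = ";"),
    entrez_id = anno$entrez_id, genbank_id = anno$genbank_id,
    stringsAsFactors = FALSE)
  storeTable(store, "ANNO", annoFlat)
  hgncFlat <- data.frame(
    approved_symbol = hgnc$approved_symbol, status = hgnc$status,
    previous_symbols = vapply(hgnc$previous_symbols, paste, character(1),
                              collapse = ";"),
    aliases = vapply(hgnc$aliases, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  storeTable(store, "HGNC", hgncFlat)
  storeTable(store, "LABELS",
             data.frame(sample = colnames(se), label = se$label,
                        stringsAsFactors = FALSE))
  invisible(store)
}
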