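# Benchmark coverage: how much of a disease reference list the pipeline
# recovered.

#' Read benchmark gene / GO-term lists
#'
#' @param genePath TSV with a \code{gene_symbol} column (one symbol per
#'   row); symbols are uppercase-normalized
#' @param termPath TSV with columns \code{term_id} and \code{domain}
#' @param sep field delimiter
#' @return list with elements \code{genes} (character) and \code{terms}
#'   (data.frame term_id, domain); an element is NULL when its path is
#'   not supplied
#' @export
readBenchmarkLists <- function(genePath = NULL, termPath = NULL,
                               sep = "\t") {
  genes <- NULL; terms <- NULL
  if (!is.null(genePath)) {
    df <- readTsv(genePath, sep = sep, colClasses = "character")
    if (!"gene_symbol" %in% names(df))
      stop("benchmark gene list needs a 'gene_symbol' column")
    genes <- sort(unique(toupper(df$gene_symbol)))
    if (!length(genes)) stop("benchmark gene list is empty")
  }
  if (!is.null(termPath)) {
    terms <- readTsv(termPath, sep = sep, colClasses = "character")
    if (!all(c("term_id", "domain") %in% names(terms)))
      stop("benchmark term list needs columns 'term_id' and 'domain'")
    terms <- unique(terms[, c("term_id", "domain")])
    if (!nrow(terms)) stop("benchmark term list is empty")
  }
  list(genes = genes, terms = terms)
}

#' Benchmark coverage of a gene list
#'
#' Coverage is |selected ∩ benchmark| / |benchmark| over unique
#' uppercase-normalized symbols (the full benchmark is always the
#' denominator for genes).
#'
#' @param selectedGenes gene symbols recovered by the pipeline
#' @param benchGenes benchmark gene symbols (non-empty)
#' @return list: n_benchmark, n_covered, coverage, restriction
#' @export
coverageGenes <- function(selectedGenes, benchGenes) {
  if (is.null(benchGenes) || !length(benchGenes))
    stop("benchmark gene list is empty")
  bench <- unique(toupper(benchGenes))
  sel <- unique(toupper(selectedGenes))
  hit <- length(intersect(sel, bench))
  list(n_benchmark = length(bench), n_covered = hit,
       coverage = hit / length(bench), restriction = "all")
}

#' Benchmark coverage of a GO-term list
#'
#' For term lists produced one GO domain at a time, the denominator is
#' restricted to the benchmark terms of that domain
#' (\code{restrict = TRUE}); enrichment-style outputs are compared against
#' all benchmark terms (\code{restrict = FALSE}).
#'
#' @param sigTerms significant term ids
#' @param benchTerms data.frame with columns term_id, domain (non-empty)
#' @param domain the analyzed GO domain
#' @param restrict restrict the denominator to `domain`
#' @return list: n_benchmark, n_covered, coverage, restriction
#' @export
coverageTerms <- function(sigTerms, benchTerms, domain = c("MF", "BP", "CC"),
                          restrict = TRUE) {
  domain <- match.arg(domain)
  if (is.null(benchTerms) || !nrow(benchTerms))
    stop("benchmark term list is empty")
  denom <- if (restrict)
    unique(benchTerms$term_id[benchTerms$domain == domain])
  else unique(benchTerms$term_id)
  if (!length(denom))
    stop("restricted benchmark denominator is empty for domain ", domain)
  hit <- length(intersect(unique(sigTerms), denom))
  list(n_benchmark = length(denom), n_covered = hit,
       coverage = hit / length(denom),
       restriction = if (restrict) "domain-restricted" else "all")
}
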