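# Synthetic fixture generation: complete offline input bundles (expression
# matrix, labels, annotations, gene names, toy GO DAG, benchmark lists)
# with controlled class signal.

#' Specify a synthetic input bundle
#'
#' Defaults describe the canonical study conditions used throughout the
#' package's own verification: 40 samples split evenly into two classes,
#' unit Gaussian noise, term sizes log-uniform between 3 and 200 probesets
#' (so both the RLS and the l1l2 route are exercised), and one informative
#' term whose designated probesets are shifted by 3 noise SDs between
#' classes.
#'
#' @param nSamples number of samples
#' @param nProbesets number of probesets on the platform
#' @param nTerms number of GO terms in the (single-domain) toy DAG,
#'   including the root
#' @param termSizeRange log-uniform range of probesets per term (capped at
#'   nProbesets)
#' @param informativeTerms list of lists with elements \code{size},
#'   \code{nInformative} and \code{effect} (class-mean gap in noise-SD
#'   units); set to \code{list()} for a pure-noise bundle
#' @param noiseSd Gaussian noise standard deviation
#' @param classBalance fraction of samples in the +1 class
#' @param domain GO domain of the toy DAG
#' @param heavyTails if TRUE, t(3) noise scaled to `noiseSd` replaces the
#'   Gaussian (robustness checks)
#' @param seed RNG seed; a fixed seed yields a byte-identical bundle
#' @return validated spec (list) for [makeBundle()]
#' @export
fixtureSpec <- function(nSamples = 40L, nProbesets = 200L, nTerms = 20L,
                        termSizeRange = c(3L, 200L),
                        informativeTerms = list(
                          list(size = 20L, nInformative = 5L, effect = 3)),
                        noiseSd = 1, classBalance = 0.5, domain = "MF",
                        heavyTails = FALSE, seed = 1L) {
  spec <- list(nSamples = as.integer(nSamples),
               nProbesets = as.integer(nProbesets),
               nTerms = as.integer(nTerms),
               termSizeRange = as.integer(termSizeRange),
               informativeTerms = informativeTerms, noiseSd = noiseSd,
               classBalance = classBalance, domain = domain,
               heavyTails = heavyTails, seed = as.integer(seed))
  stopifnot(spec$nSamples >= 4L, spec$nProbesets >= 3L, spec$nTerms >= 3L,
            length(spec$termSizeRange) == 2L,
            spec$termSizeRange[1L] >= 1L,
            spec$termSizeRange[2L] >= spec$termSizeRange[1L],
            spec$noiseSd > 0, spec$classBalance > 0, spec$classBalance < 1,
            spec$domain %in% c("MF", "BP", "CC"))
  for (it in spec$informativeTerms) {
    if (is.null(it$size) || is.null(it$nInformative) || is.null(it$effect))
      stop("each informative term needs size, nInformative and effect")
    if (it$effect < 0) stop("effect size must be >= 0")
    if (it$nInformative > it$size)
      stop("informative probeset count (", it$nInformative,
           ") exceeds term size (", it$size, ")")
    if (length(spec$informativeTerms) + 1L > spec$nTerms - 1L)
      stop("more informative terms than available non-root terms")
  }
  spec
}

#' Generate a toy GO DAG with enumerated ground truth
#'
#' Builds a single-domain DAG as a random rooted tree plus extra is_a
#' edges (always towards lower term indices, so acyclicity holds by
#' construction), assigns random direct annotation counts, and computes
#' the expected information content of every term by exhaustive
#' descendant enumeration (iterated closure over the child lists),
#' independently of the package's graph machinery.  The manifest is the
#' oracle the IC implementation is checked against.
#'
#' @param nTerms number of terms including the root (>= 3)
#' @param seed RNG seed
#' @param domain GO domain of all terms
#' @param extraEdgeProb probability a non-root term gains a second parent
#' @return list: terms (data.frame), edges (child/parent data.frame),
#'   dag ([GODag-class]), corpus (direct counts), expectedIC (named
#'   vector from the enumeration oracle)
#' @export
makeToyDag <- function(nTerms, seed = 1L, domain = "MF",
                       extraEdgeProb = 0.25) {
  stopifnot(nTerms >= 3L)
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(nTerms))
  terms <- data.frame(id = ids,
                      name = c(paste0(tolower(domain), " root"),
                               paste0("toy term ", seq_len(nTerms - 1L))),
                      domain = domain, stringsAsFactors = FALSE)
  child <- character(); parent <- character()
  for (i in 2L:nTerms) {
    p <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
    child <- c(child, ids[i]); parent <- c(parent, ids[p])
    if (i > 2L && runif(1) < extraEdgeProb) {
      q <- sample.int(i - 1L, 1L)
      if (q != p) {
        child <- c(child, ids[i]); parent <- c(parent, ids[q])
      }
    }
  }
  edges <- data.frame(child = child, parent = parent,
                      stringsAsFactors = FALSE)
  counts <- setNames(sample(0:3, nTerms, replace = TRUE), ids)
  if (sum(counts) == 0) counts[nTerms] <- 1
  # enumeration oracle: descendants by iterated expansion of child lists
  childrenOf <- split(edges$child, edges$parent)
  descend <- function(t) {
    seen <- t
    frontier <- t
    while (length(frontier)) {
      nxt <- setdiff(unlist(childrenOf[frontier], use.names = FALSE), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  subsumed <- vapply(ids, function(t) sum(counts[descend(t)]), numeric(1))
  expectedIC <- -log(subsumed / subsumed[[ids[1L]]])
  expectedIC[!is.finite(expectedIC)] <- NA_real_
  dag <- newGODag(terms, edges)
  validObject(dag)
  list(terms = terms, edges = edges, dag = dag, corpus = counts,
       expectedIC = expectedIC)
}

# Draw noise values for the expression matrix.
drawNoise <- function(n, sd, heavyTails) {
  if (heavyTails) stats::rt(n, df = 3) / sqrt(3) * sd else rnorm(n, 0, sd)
}

#' Generate a complete synthetic input bundle
#'
#' Writes every file the ingestion layer consumes: expression matrix
#' (gedm.tsv), labels (labels.tsv, raw strings "case"/"control"),
#' platform annotations (annotations.tsv), gene-name table
#' (gene_names.tsv), toy GO graph (go.obo), benchmark lists
#' (benchmark_genes.tsv / benchmark_terms.tsv), a ready-to-run
#' config.yaml and a manifest.json with the ground truth (informative
#' terms/probesets, contaminated terms, expected IC values).
#'
#' Expression values are baseline noise; the designated informative
#' probesets of each informative term get a +effect*noiseSd shift in the
#' +1 class, so their class-mean gap is effect noise-SDs.  Because term
#' subsets overlap by construction, noise terms can contain informative
#' probesets; such "contaminated" terms are listed in the manifest so
#' that recovery statistics can exclude them from the pure-noise pool.
#'
#' @param spec a validated spec from [fixtureSpec()]
#' @param outdir output directory (created)
#' @return named list of file paths (plus `manifest`, the parsed ground
#'   truth), invisibly
#' @export
makeBundle <- function(spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  nInf <- length(spec$informativeTerms)

  toy <- makeToyDag(spec$nTerms, seed = spec$seed + 7L,
                    domain = spec$domain)
  set.seed(spec$seed + 13L)
  ids <- toy$terms$id
  root <- ids[1L]
  nonRoot <- ids[-1L]

  # term sizes: informative terms take the first non-root slots with their
  # specified sizes; the rest are log-uniform in termSizeRange
  sizes <- setNames(integer(length(nonRoot)), nonRoot)
  lo <- spec$termSizeRange[1L]
  hi <- min(spec$termSizeRange[2L], spec$nProbesets)
  sizes[] <- pmin(round(exp(runif(length(nonRoot), log(lo), log(hi)))),
                  spec$nProbesets)
  sizes[sizes < 1L] <- 1L
  infTermIds <- character()
  for (i in seq_len(nInf)) {
    sizes[nonRoot[i]] <- min(spec$informativeTerms[[i]]$size,
                             spec$nProbesets)
    infTermIds <- c(infTermIds, nonRoot[i])
  }

  probesets <- sprintf("PS%05d", seq_len(spec$nProbesets))
  term2ps <- lapply(sizes, function(s) sort(sample(probesets, s)))

  # labels
  nPos <- round(spec$classBalance * spec$nSamples)
  stopifnot(nPos >= 2L, spec$nSamples - nPos >= 2L)
  samples <- sprintf("S%03d", seq_len(spec$nSamples))
  y <- sample(c(rep(1, nPos), rep(-1, spec$nSamples - nPos)))

  # expression: baseline noise + informative shifts
  vals <- matrix(drawNoise(spec$nProbesets * spec$nSamples, spec$noiseSd,
                           spec$heavyTails),
                 nrow = spec$nProbesets,
                 dimnames = list(probesets, samples))
  infPs <- character()
  for (i in seq_len(nInf)) {
    it <- spec$informativeTerms[[i]]
    ps <- term2ps[[infTermIds[i]]][seq_len(it$nInformative)]
    vals[ps, y == 1] <- vals[ps, y == 1] + it$effect * spec$noiseSd
    infPs <- union(infPs, ps)
  }
  contaminated <- names(term2ps)[vapply(term2ps, function(p)
    any(p %in% infPs), logical(1))]
  contaminated <- setdiff(contaminated, infTermIds)
  # 6-decimal values are written verbatim, so file and memory agree exactly
  vals <- round(vals, 6)

  # annotations + gene names (a slice of probesets carries an outdated
  # platform symbol resolvable through the previous-symbols column)
  geneOf <- setNames(sprintf("GW%04d", seq_len(spec$nProbesets)), probesets)
  platformSym <- geneOf
  nOld <- max(1L, round(0.05 * spec$nProbesets))
  oldIdx <- sort(sample(spec$nProbesets, nOld))
  platformSym[oldIdx] <- paste0("OLD", geneOf[oldIdx])
  goCell <- vapply(probesets, function(p) {
    tm <- names(term2ps)[vapply(term2ps, function(x) p %in% x, logical(1))]
    paste(tm, collapse = ";")
  }, character(1))
  genbank <- sprintf("NM_%06d", seq_len(spec$nProbesets))
  genbank[sample(spec$nProbesets, max(1L, spec$nProbesets %/% 10L))] <- NA
  anno <- data.frame(probeset_id = probesets,
                     gene_symbol = unname(platformSym),
                     go_terms = unname(goCell),
                     entrez_id = as.character(1000L + seq_len(spec$nProbesets)),
                     genbank_id = genbank, stringsAsFactors = FALSE)

  hgnc <- data.frame(approved_symbol = unname(geneOf), status = "approved",
                     previous_symbols = "", aliases = "",
                     stringsAsFactors = FALSE)
  hgnc$previous_symbols[oldIdx] <- paste0("OLD", geneOf[oldIdx])
  aliasIdx <- setdiff(sample(spec$nProbesets, min(3L, spec$nProbesets)),
                      oldIdx)
  hgnc$aliases[aliasIdx] <- paste0("ALT", geneOf[aliasIdx])

  # benchmark lists: informative genes/terms plus decoys
  infGenes <- unique(unname(geneOf[infPs]))
  decoyGenes <- setdiff(unname(geneOf), infGenes)
  decoyGenes <- sort(sample(decoyGenes, min(10L, length(decoyGenes))))
  benchGenes <- data.frame(
    gene_symbol = c(infGenes, decoyGenes, "GWEXT01", "GWEXT02"),
    stringsAsFactors = FALSE)
  decoyTerms <- sort(sample(setdiff(nonRoot, infTermIds),
                            min(4L, length(nonRoot) - nInf)))
  otherDomain <- setdiff(c("MF", "BP", "CC"), spec$domain)[1L]
  benchTerms <- data.frame(
    term_id = c(infTermIds, decoyTerms,
                sprintf("GO:%07d", 9000001:9000002)),
    domain = c(rep(spec$domain, length(infTermIds) + length(decoyTerms)),
               rep(otherDomain, 2L)),
    stringsAsFactors = FALSE)

  # write everything
  paths <- list(
    gedm = file.path(outdir, "gedm.tsv"),
    labels = file.path(outdir, "labels.tsv"),
    annotations = file.path(outdir, "annotations.tsv"),
    gene_names = file.path(outdir, "gene_names.tsv"),
    go = file.path(outdir, "go.obo"),
    benchmark_genes = file.path(outdir, "benchmark_genes.tsv"),
    benchmark_terms = file.path(outdir, "benchmark_terms.tsv"),
    config = file.path(outdir, "config.yaml"),
    manifest = file.path(outdir, "manifest.json"))

  writeTsv(data.frame(probeset_id = probesets, vals, check.names = FALSE),
           paths$gedm)
  writeTsv(data.frame(sample = samples,
                      label = ifelse(y == 1, "case", "control")),
           paths$labels)
  writeTsv(anno, paths$annotations)
  writeTsv(hgnc, paths$gene_names)
  writeObo(toy$terms, toy$edges, paths$go)
  writeTsv(benchGenes, paths$benchmark_genes)
  writeTsv(benchTerms, paths$benchmark_terms)

  config <- list(
    inputs = list(gedm = "gedm.tsv", labels = "labels.tsv",
                  annotations = "annotations.tsv",
                  gene_names = "gene_names.tsv", go = "go.obo",
                  go_format = "obo"),
    columns = list(probeset = "probeset_id", symbol = "gene_symbol",
                   go = "go_terms", entrez = "entrez_id",
                   genbank = "genbank_id"),
    separators = list(field = "\t", go = ";", multi = ";"),
    class_map = list(case = 1, control = -1),
    domain = spec$domain)
  yaml::write_yaml(config, paths$config)

  manifest <- list(
    seed = spec$seed, n_samples = spec$nSamples,
    n_probesets = spec$nProbesets, domain = spec$domain,
    noise_sd = spec$noiseSd,
    informative_terms = infTermIds,
    informative_probesets = sort(infPs),
    contaminated_terms = sort(contaminated),
    term_sizes = as.list(sizes),
    expected_ic = as.list(toy$expectedIC),
    corpus = as.list(toy$corpus))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  out <- paths
  out$manifest_data <- manifest
  out$values <- vals
  out$labels_vec <- setNames(y, samples)
  out$anno_table <- anno
  invisible(out)
}
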