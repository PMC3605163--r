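# The two pipeline phases operating on a shared ensemble directory:
# runExperiment (ingest, integrate, subset, learn) and runPostprocess
# (significance, outputs, semantics, benchmark).

# ---- result (de)serialization --------------------------------------------

resultToList <- function(res) {
  list(term_id = termId(res), technique = technique(res),
       probeset_ids = res@probesetIds, outer_k = res@outerK,
       n_samples = res@nSamples,
       per_mu = lapply(perMu(res), function(e) list(
         mu = e$mu,
         mean_test_error = e$mean_test_error,
         sd_test_error = e$sd_test_error,
         median_test_error = e$median_test_error,
         mean_train_error = e$mean_train_error,
         sd_train_error = e$sd_train_error,
         frequencies = as.list(e$frequencies),
         splits = lapply(e$splits, function(s) list(
           split_index = s$split_index,
           selected_variables = as.list(s$selected_variables),
           chosen_l1 = s$chosen_l1,
           test_error = s$test_error,
           train_error = s$train_error,
           confusion = as.list(s$confusion))))))
}

resultFromList <- function(x) {
  perMu <- lapply(x$per_mu, function(e) {
    fr <- setNames(as.integer(unlist(e$frequencies)), names(e$frequencies))
    splits <- lapply(e$splits, function(s) list(
      split_index = as.integer(s$split_index),
      selected_variables = as.character(unlist(s$selected_variables)),
      chosen_l1 = if (is.null(s$chosen_l1)) NA_real_
                  else as.numeric(s$chosen_l1),
      test_error = as.numeric(s$test_error),
      train_error = as.numeric(s$train_error),
      confusion = setNames(as.numeric(unlist(s$confusion)),
                           names(s$confusion))))
    list(mu = if (is.null(e$mu)) NA_real_ else as.numeric(e$mu),
         splits = splits, frequencies = fr,
         mean_test_error = as.numeric(e$mean_test_error),
         sd_test_error = as.numeric(e$sd_test_error),
         median_test_error = as.numeric(e$median_test_error),
         mean_train_error = as.numeric(e$mean_train_error),
         sd_train_error = as.numeric(e$sd_train_error))
  })
  new("SelectionResult", termId = x$term_id, technique = x$technique,
      perMu = perMu, probesetIds = as.character(unlist(x$probeset_ids)),
      outerK = as.integer(x$outer_k), nSamples = as.integer(x$n_samples))
}

termFileName <- function(termId) gsub("[^A-Za-z0-9_.-]", "_", termId)

# ---- configuration --------------------------------------------------------

#' Read a pipeline configuration file
#'
#' YAML with blocks \code{inputs} (paths relative to the config file:
#' gedm, labels, annotations, gene_names, go, go_format, optional
#' benchmark_genes / benchmark_terms), \code{columns}, \code{separators}
#' (field, go, multi), \code{class_map} (raw label -> -1/+1) and
#' \code{domain}, plus optional \code{solver} overrides (mu_values,
#' inner_k, outer_k, n_l1, seed, ...) and optional \code{propagate},
#' \code{ratio_threshold}, \code{min_probesets}.
#'
#' @param path config file path
#' @return config list with resolved absolute input paths
#' @export
readConfig <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (nm in names(cfg$inputs)) {
    if (nm == "go_format") next
    p <- cfg$inputs[[nm]]
    if (!is.null(p) && !grepl("^/", p))
      cfg$inputs[[nm]] <- file.path(base, p)
  }
  cfg
}

solverConfigFromList <- function(x, seed = NULL) {
  x <- x %||% list()
  solverConfig(
    muValues = x$mu_values %||% c(1e-3, 1e-2, 1e-1),
    l1Grid = x$l1_grid %||% numeric(),
    nL1 = x$n_l1 %||% 20L,
    l1MinRatio = x$l1_min_ratio %||% 1e-3,
    innerK = x$inner_k %||% 3L,
    outerK = x$outer_k %||% 4L,
    tol = x$tol %||% 1e-6,
    maxIter = x$max_iter %||% 20000L,
    seed = seed %||% x$seed %||% 101L,
    standardize = x$standardize %||% TRUE)
}

# ---- experiment phase -----------------------------------------------------

#' Run the experiment phase
#'
#' Ingests all inputs, persists raw and derived tables in the ensemble's
#' relational store, masks the expression matrix per GO term, routes each
#' subset, runs the knowledge-discovery tasks and writes one result file
#' per term.  The ensemble is marked complete only when every step
#' succeeded; rerunning with the same config and seed reproduces the
#' result files byte for byte, for any worker count.
#'
#' @param configPath path to a YAML config (see [readConfig()])
#' @param ensembleDir output ensemble directory
#' @param seed master seed (overrides the config's solver seed)
#' @param workers parallel workers for the discovery tasks
#' @return invisibly, a list with the ensemble dir, subsets manifest and
#'   results
#' @export
runExperiment <- function(configPath, ensembleDir, seed = NULL,
                          workers = 1L) {
  cfg <- readConfig(configPath)
  for (nm in c("gedm", "labels", "annotations", "gene_names", "go")) {
    p <- cfg$inputs[[nm]]
    if (is.null(p) || !file.exists(p))
      stop("input '", nm, "' missing or not found: ",
           if (is.null(p)) "<unset>" else p)
  }
  dir.create(ensembleDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("store", "results", "postprocess", "logs"))
    dir.create(file.path(ensembleDir, d), showWarnings = FALSE)
  logfile <- file.path(ensembleDir, "logs", "experiment.log")
  unlink(file.path(ensembleDir, "COMPLETE"))
  log <- function(...) gowiseLog(..., logfile = logfile,
                                 phase = "experiment")

  fieldSep <- cfg$separators$field %||% "\t"
  se <- readGEDM(cfg$inputs$gedm, sep = fieldSep)
  log("GEDM: ", nrow(se), " probesets x ", ncol(se), " samples")
  classMap <- unlist(cfg$class_map)
  labels <- readLabels(cfg$inputs$labels, classMap, sep = fieldSep)
  se <- attachLabels(se, labels)
  log("labels: ", sum(se$label == 1), " / ", sum(se$label == -1),
      " per class")
  columns <- unlist(cfg$columns %||%
    list(probeset = "probeset_id", symbol = "gene_symbol",
         go = "go_terms", entrez = "entrez_id", genbank = "genbank_id"))
  anno <- readAnnotations(cfg$inputs$annotations, columns = columns,
                          goSep = cfg$separators$go %||% ";",
                          sep = fieldSep)
  log("annotations: ", nrow(anno), " probesets")
  hgnc <- readGeneNames(cfg$inputs$gene_names,
                        multiSep = cfg$separators$multi %||% ";",
                        sep = fieldSep)
  dag <- readGODag(cfg$inputs$go,
                   format = cfg$inputs$go_format %||% "obo")
  log("GO DAG: ", nrow(goTerms(dag)), " terms")

  store <- createStore(file.path(ensembleDir, "store"))
  loadRawTables(store, se, anno, hgnc)
  domain <- cfg$domain %||% "MF"
  map <- buildTermProbesetMap(anno, dag, domain = domain,
                              propagate = isTRUE(cfg$propagate),
                              probesets = rownames(se))
  p2g <- buildProbesetToGene(anno, hgnc)
  storeDerivedTables(store, map, p2g)
  log("derived tables: ", length(termToProbesets(map)), " mapped terms")

  subsets <- generateSubsets(se, map,
                             ratioThreshold = cfg$ratio_threshold %||% 1.0,
                             minProbesets = cfg$min_probesets %||% 1L)
  manifest <- subsetManifest(subsets)
  writeTsv(manifest, file.path(ensembleDir, "subset_manifest.tsv"))
  log("subsets: ", nrow(manifest), " (",
      sum(manifest$technique == "RLS"), " RLS, ",
      sum(manifest$technique == "L1L2FS"), " L1L2FS)")

  scfg <- solverConfigFromList(cfg$solver, seed = seed)
  sel <- setNames(unname(labels[colnames(se)]), colnames(se))
  results <- runDiscovery(subsets, sel, scfg, workers = workers)
  for (res in results)
    jsonlite::write_json(resultToList(res),
                         file.path(ensembleDir, "results",
                                   paste0(termFileName(termId(res)),
                                          ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  log("discovery: ", length(results), " term results written")

  snapshot <- cfg
  snapshot$solver <- utils::modifyList(
    cfg$solver %||% list(),
    list(seed = scfg@seed, outer_k = scfg@outerK, inner_k = scfg@innerK,
         mu_values = scfg@muValues))
  yaml::write_yaml(snapshot, file.path(ensembleDir, "config_snapshot.yaml"))
  writeLines("complete", file.path(ensembleDir, "COMPLETE"))
  invisible(list(dir = ensembleDir, manifest = manifest,
                 results = results, map = map, p2g = p2g, dag = dag,
                 se = se))
}

loadEnsembleResults <- function(ensembleDir) {
  files <- sort(list.files(file.path(ensembleDir, "results"),
                           pattern = "\\.json$", full.names = TRUE))
  res <- lapply(files, function(f)
    resultFromList(jsonlite::read_json(f)))
  setNames(res, vapply(res, termId, character(1)))
}

# ---- postprocess phase ----------------------------------------------------

#' Run the postprocess phase
#'
#' Works on a completed ensemble (refuses an incomplete one): calls
#' significant terms, writes per-mu significant and unified term lists,
#' per-term properly-selected variable lists, selected / not-selected
#' histograms and error statistics; when at least two significant terms
#' exist for a mu, clusters them by normalized Resnik similarity and
#' emits the colored minimal subgraph as DOT; when benchmark lists are
#' supplied, writes the coverage report.  All outputs are plain TSV/DOT
#' under \code{postprocess/} and reproduce byte-identically on a rerun.
#'
#' @param ensembleDir completed ensemble directory
#' @param errorThreshold significance threshold on the mean outer test
#'   error (strictly below; default 0.30)
#' @param freqThreshold properly-selected frequency threshold as a
#'   fraction of the outer fold count (strictly above; default 0.5)
#' @param semanticThreshold similarity threshold of the flat cluster cut
#' @param linkage hierarchical-clustering linkage
#' @param benchmarkGenes,benchmarkTerms optional benchmark list paths
#'   (override the config snapshot's entries)
#' @return invisibly, a list with verdicts, unified lists, histograms,
#'   error stats, cluster assignments and coverage
#' @export
runPostprocess <- function(ensembleDir, errorThreshold = 0.30,
                           freqThreshold = 0.5, semanticThreshold = 0.8,
                           linkage = "average", benchmarkGenes = NULL,
                           benchmarkTerms = NULL) {
  if (!file.exists(file.path(ensembleDir, "COMPLETE")))
    stop("ensemble at ", ensembleDir,
         " is incomplete; run the experiment phase first")
  cfg <- yaml::read_yaml(file.path(ensembleDir, "config_snapshot.yaml"))
  domain <- cfg$domain %||% "MF"
  outDir <- file.path(ensembleDir, "postprocess")
  dir.create(outDir, showWarnings = FALSE)
  logfile <- file.path(ensembleDir, "logs", "postprocess.log")
  log <- function(...) gowiseLog(..., logfile = logfile,
                                 phase = "postprocess")

  results <- loadEnsembleResults(ensembleDir)
  if (!length(results)) stop("no results in ensemble")
  store <- openStore(file.path(ensembleDir, "store"))
  t2p <- fetchTable(store, "term2probeset")
  fwd <- lapply(split(t2p$probeset_id, t2p$term_id), function(x)
    sort(unique(x)))
  map <- new("TermProbesetMap", term2probeset = fwd[sort(names(fwd))],
             probeset2term = invertMap(fwd), domain = domain)
  p2gTab <- fetchTable(store, "probeset2gene")
  p2g <- new("ProbesetGeneMap", map = p2gTab)
  allProbesets <- fetchTable(store, "GEDM")$probeset_id
  dag <- if (!is.null(cfg$inputs$go) && file.exists(cfg$inputs$go))
    readGODag(cfg$inputs$go, format = cfg$inputs$go_format %||% "obo")
  else NULL
  nDomainTerms <- if (!is.null(dag))
    sum(goTerms(dag)$domain == domain) else length(fwd)

  verdicts <- callSignificance(results, errorThreshold)
  writeTsv(verdicts, file.path(outDir, "verdicts.tsv"))
  errStats <- summarizeErrors(results)
  writeTsv(errStats$per_mu, file.path(outDir, "error_stats_per_mu.tsv"))
  writeTsv(errStats$per_term, file.path(outDir, "error_stats_per_term.tsv"))

  muKeys <- setdiff(sort(unique(verdicts$source)), "RLS")
  unified <- list(); clusters <- list()
  for (key in c(muKeys, if ("RLS" %in% verdicts$source) "RLS")) {
    sig <- verdicts[verdicts$significant & verdicts$source == key, ,
                    drop = FALSE]
    writeTsv(sig, file.path(outDir, paste0("significant_", key, ".tsv")))
    # per-term properly-selected variable lists with annotations
    varRows <- lapply(sig$term_id, function(t) {
      res <- results[[t]]
      sel <- selectVariables(res, key, TRUE, freqThreshold)
      if (!length(sel)) return(NULL)
      fr <- if (technique(res) == "L1L2FS")
        selectionFrequencies(res, key) else NULL
      df <- annotateVariables(sel, p2g, frequencies = fr)
      cbind(term_id = t, df, stringsAsFactors = FALSE)
    })
    varRows <- varRows[!vapply(varRows, is.null, logical(1))]
    varTab <- if (length(varRows)) {
      tmp <- lapply(varRows, function(d) {
        if (!"frequency" %in% names(d)) d$frequency <- NA_integer_
        d
      })
      do.call(rbind, tmp)
    } else data.frame(term_id = character(), probeset_id = character(),
                      gene_symbol = character(), status = character(),
                      entrez_id = character(), genbank_id = character(),
                      frequency = integer(), stringsAsFactors = FALSE)
    writeTsv(varTab, file.path(outDir, paste0("variables_", key, ".tsv")))

    hist <- buildHistograms(results, verdicts, key, allProbesets,
                            nDomainTerms, freqThreshold, p2g)
    writeTsv(hist$selected,
             file.path(outDir, paste0("hist_selected_", key, ".tsv")))
    if (!is.null(hist$not_selected))
      writeTsv(hist$not_selected,
               file.path(outDir, paste0("hist_notselected_", key, ".tsv")))
    writeTsv(as.data.frame(hist$meta),
             file.path(outDir, paste0("hist_meta_", key, ".tsv")))

    if (key != "RLS") {
      uni <- buildUnifiedList(results, verdicts, key, dag = dag,
                              freqThreshold = freqThreshold)
      unified[[key]] <- uni
      writeTsv(uni, file.path(outDir, paste0("unified_", key, ".tsv")))
      # semantic clustering of the significant terms for this mu
      sigTerms <- unique(uni$term_id)
      if (length(sigTerms) >= 2L && !is.null(dag)) {
        corpus <- annotationCorpus(map)
        ic <- suppressWarnings(computeIC(dag, corpus, domain))
        simTry <- tryCatch(
          suppressWarnings(buildSimilarityMatrix(dag, ic, sigTerms)),
          error = function(e) NULL)
        if (!is.null(simTry)) {
          cl <- clusterTerms(simTry, semanticThreshold, linkage)
          clusters[[key]] <- cl
          writeTsv(data.frame(term_id = names(cl),
                              cluster = unname(cl)),
                   file.path(outDir, paste0("clusters_", key, ".tsv")))
          writeTsv(data.frame(term_id = rownames(simTry),
                              as.data.frame(simTry), check.names = FALSE),
                   file.path(outDir, paste0("similarity_", key, ".tsv")))
          sg <- minimalSubgraph(dag, rownames(simTry))
          writeLines(emitDot(sg, cl),
                     file.path(outDir, paste0("subgraph_", key, ".dot")))
        }
      } else if (length(sigTerms) == 1L) {
        log("mu ", key, ": single significant term, clustering skipped")
      }
    }
  }

  bg <- benchmarkGenes %||% cfg$inputs$benchmark_genes
  bt <- benchmarkTerms %||% cfg$inputs$benchmark_terms
  coverage <- NULL
  if (!is.null(bg) || !is.null(bt)) {
    bench <- readBenchmarkLists(bg, bt)
    covRows <- list()
    for (key in names(unified)) {
      uni <- unified[[key]]
      if (!is.null(bench$genes)) {
        vt <- readTsv(file.path(outDir, paste0("variables_", key, ".tsv")))
        rlsPath <- file.path(outDir, "variables_RLS.tsv")
        if (file.exists(rlsPath)) {
          rt <- readTsv(rlsPath)
          if (nrow(rt)) vt <- rbind(vt, rt)
        }
        genes <- unique(stats::na.omit(vt$gene_symbol))
        cg <- coverageGenes(genes, bench$genes)
        covRows[[length(covRows) + 1L]] <- data.frame(
          source = key, kind = "genes", restriction = cg$restriction,
          n_benchmark = cg$n_benchmark, n_covered = cg$n_covered,
          coverage = cg$coverage, stringsAsFactors = FALSE)
      }
      if (!is.null(bench$terms)) {
        ct <- coverageTerms(unique(uni$term_id), bench$terms, domain,
                            restrict = TRUE)
        covRows[[length(covRows) + 1L]] <- data.frame(
          source = key, kind = "terms", restriction = ct$restriction,
          n_benchmark = ct$n_benchmark, n_covered = ct$n_covered,
          coverage = ct$coverage, stringsAsFactors = FALSE)
      }
    }
    coverage <- do.call(rbind, covRows)
    if (!is.null(coverage))
      writeTsv(coverage, file.path(outDir, "coverage.tsv"))
  }
  log("postprocess complete: ",
      sum(verdicts$significant), " significant (term, source) pairs")
  invisible(list(verdicts = verdicts, unified = unified,
                 clusters = clusters, error_stats = errStats,
                 coverage = coverage))
}
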