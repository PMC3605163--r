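# Simulation studies used to verify the pipeline's operating
# characteristics on synthetic bundles: signal recovery under the
# canonical study conditions and error calibration on pure noise.

#' Informative-term recovery study
#'
#' Runs the full discovery chain (bundle generation, ingestion,
#' integration, masking, nested-CV learning, significance calls) on
#' repeated synthetic bundles holding one informative term (5 informative
#' probesets at a 3-SD class gap among 40 samples), and reports per
#' replicate whether the informative term was called significant, whether
#' all its informative probesets reached the maximum selection frequency,
#' and how often pure-noise terms (terms containing no informative
#' probeset) were called significant.
#'
#' @param nSeeds number of independent replicates
#' @param seed base seed; replicate r uses seed + r
#' @param errorThreshold significance threshold (default 0.30)
#' @param infSize subset size of the informative term (default 60, above
#'   the sample count so the term takes the l1l2 route)
#' @param nInformative number of shifted probesets (default 5)
#' @param effect class-mean gap in noise SDs (default 3)
#' @param cfg solver configuration; default uses a single mu of 0.5 (a
#'   deliberately high correlation penalty, since the study's target is
#'   co-selection of the correlated informative group), a 10-point l1
#'   grid, 3 inner and 4 outer folds
#' @param workers parallel workers for the per-term tasks
#' @return data.frame with one row per replicate: informative_significant,
#'   informative_freq_max (all informative probesets at frequency =
#'   outerK), n_noise_terms, n_noise_significant
#' @export
runRecoveryStudy <- function(nSeeds = 20L, seed = 1L,
                             errorThreshold = 0.30, infSize = 60L,
                             nInformative = 5L, effect = 3,
                             cfg = NULL, workers = 1L) {
  if (is.null(cfg))
    cfg <- solverConfig(muValues = 0.5, nL1 = 10L, innerK = 3L,
                        outerK = 4L, tol = 1e-5, seed = seed)
  rows <- vector("list", nSeeds)
  for (r in seq_len(nSeeds)) {
    spec <- fixtureSpec(
      nSamples = 40L, nProbesets = 150L, nTerms = 8L,
      termSizeRange = c(3L, 60L),
      informativeTerms = list(list(size = infSize,
                                   nInformative = nInformative,
                                   effect = effect)),
      seed = seed + r)
    dir <- tempfile("recovery")
    b <- makeBundle(spec, dir)
    se <- attachLabels(readGEDM(b$gedm),
                       readLabels(b$labels, c(case = 1, control = -1)))
    dag <- readGODag(b$go, format = "obo")
    anno <- readAnnotations(b$annotations)
    map <- buildTermProbesetMap(anno, dag, spec$domain,
                                probesets = rownames(se))
    subsets <- generateSubsets(se, map)
    labels <- setNames(se$label, colnames(se))
    taskCfg <- cfg
    taskCfg@seed <- deriveSeed(cfg@seed, paste0("replicate", r))
    results <- suppressWarnings(
      runDiscovery(subsets, labels, taskCfg, workers = workers))
    verdicts <- callSignificance(results, errorThreshold)

    infTerm <- b$manifest_data$informative_terms[1]
    infPs <- b$manifest_data$informative_probesets
    noiseTerms <- setdiff(names(subsets),
                          c(infTerm, b$manifest_data$contaminated_terms))
    infSig <- any(verdicts$significant & verdicts$term_id == infTerm)
    freqMax <- FALSE
    if (infTerm %in% names(results) &&
        technique(results[[infTerm]]) == "L1L2FS") {
      fr <- selectionFrequencies(results[[infTerm]], "mu1")
      freqMax <- all(fr[infPs] == taskCfg@outerK)
    }
    noiseSig <- sum(vapply(noiseTerms, function(t)
      any(verdicts$significant & verdicts$term_id == t), logical(1)))
    unlink(dir, recursive = TRUE)
    rows[[r]] <- data.frame(replicate = r,
                            informative_significant = infSig,
                            informative_freq_max = freqMax,
                            n_noise_terms = length(noiseTerms),
                            n_noise_significant = noiseSig)
  }
  do.call(rbind, rows)
}

#' Pure-noise error calibration
#'
#' Monte-Carlo check of the cross-validated error estimate: on subsets of
#' i.i.d. Gaussian noise with random balanced labels the mean outer-fold
#' test error should sit near chance (0.5).
#'
#' @param nSubsets number of independent noise subsets
#' @param seed base seed
#' @param pX,nSamples subset dimensions (defaults 60 x 40)
#' @param technique "L1L2FS" (nested CV with selection) or "RLS"
#' @param cfg solver configuration; default as in [runRecoveryStudy()]
#' @return numeric vector of per-subset mean test errors
#' @export
noiseCalibration <- function(nSubsets = 50L, seed = 1L, pX = 60L,
                             nSamples = 40L,
                             technique = c("L1L2FS", "RLS"), cfg = NULL) {
  technique <- match.arg(technique)
  if (is.null(cfg))
    cfg <- solverConfig(muValues = 0.01, nL1 = 10L, innerK = 3L,
                        outerK = 4L, tol = 1e-5, seed = seed)
  errs <- numeric(nSubsets)
  for (i in seq_len(nSubsets)) {
    set.seed(deriveSeed(seed, paste0("noise", i)))
    vals <- matrix(rnorm(pX * nSamples), nrow = pX,
                   dimnames = list(sprintf("NP%04d", seq_len(pX)),
                                   sprintf("NS%03d", seq_len(nSamples))))
    y <- sample(rep(c(-1, 1), length.out = nSamples))
    labels <- setNames(y, colnames(vals))
    sub <- new("TermSubset", termId = sprintf("GO:NOISE%03d", i),
               values = vals, technique = technique)
    taskCfg <- cfg
    taskCfg@seed <- deriveSeed(cfg@seed, paste0("noisetask", i))
    res <- suppressWarnings(
      if (technique == "RLS") runRLSTask(sub, labels, taskCfg)
      else runL1L2Task(sub, labels, taskCfg))
    key <- if (technique == "RLS") "RLS" else "mu1"
    errs[i] <- meanTestError(res, key)
  }
  errs
}
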