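# Masking the expression matrix per GO term and routing each subset to a
# learning technique.

#' Route a subset to a learning technique
#'
#' Small subsets, where the number of variables is roughly the number of
#' samples, need no full model selection and are classified with plain
#' regularized least squares; larger subsets get embedded l1l2 feature
#' selection with nested cross-validation.  Routing is a pure function of
#' (P_X, N, threshold): RLS iff P_X <= ratioThreshold * N (boundary
#' inclusive).
#'
#' @param pX number of variables in the subset
#' @param nSamples number of samples
#' @param ratioThreshold multiplier of N below which RLS is used
#' @return "RLS" or "L1L2FS"
#' @export
routeTechnique <- function(pX, nSamples, ratioThreshold = 1.0) {
  stopifnot(nSamples >= 2, pX >= 1, ratioThreshold > 0)
  if (pX <= ratioThreshold * nSamples) "RLS" else "L1L2FS"
}

#' Generate per-term expression subsets
#'
#' Masks the expression matrix once per GO term of the map, copying the
#' rows of the annotated probesets verbatim (subsets overlap by
#' construction, following the GO structure).  Terms whose probesets are
#' all absent from the matrix are skipped with a log entry.
#'
#' @param se labeled expression SummarizedExperiment
#' @param map a [TermProbesetMap-class]
#' @param ratioThreshold routing threshold, see [routeTechnique()]
#' @param minProbesets optional minimum subset size; smaller subsets are
#'   skipped (default 1 = no filter)
#' @return named list of [TermSubset-class], one per surviving term
#' @export
generateSubsets <- function(se, map, ratioThreshold = 1.0,
                            minProbesets = 1L) {
  vals <- SummarizedExperiment::assay(se, "exprs")
  fwd <- termToProbesets(map)
  out <- list()
  for (t in names(fwd)) {
    ps <- intersect(fwd[[t]], rownames(vals))
    if (length(ps) < max(1L, minProbesets)) {
      gowiseLog("term ", t, " skipped: ", length(ps),
                " probeset(s) available", phase = "subsetting")
      next
    }
    sub <- vals[ps, , drop = FALSE]
    out[[t]] <- new("TermSubset", termId = t, values = sub,
                    technique = routeTechnique(nrow(sub), ncol(sub),
                                               ratioThreshold))
  }
  out
}

#' Subset manifest
#'
#' @param subsets list of [TermSubset-class] from [generateSubsets()]
#' @return data.frame with columns term_id, p_x, technique
#' @export
subsetManifest <- function(subsets) {
  data.frame(term_id = vapply(subsets, termId, character(1)),
             p_x = vapply(subsets, function(s) nrow(subsetValues(s)),
                          integer(1)),
             technique = vapply(subsets, technique, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
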