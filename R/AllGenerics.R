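# Accessor generics for the central classes.

#' Term identifier of a subset or result
#' @param object a [TermSubset-class] or [SelectionResult-class]
#' @return character term id
#' @export
setGeneric("termId", function(object) standardGeneric("termId"))

#' @rdname termId
#' @export
setMethod("termId", "TermSubset", function(object) object@termId)
#' @rdname termId
#' @export
setMethod("termId", "SelectionResult", function(object) object@termId)

#' Learning technique of a subset or result
#' @param object a [TermSubset-class] or [SelectionResult-class]
#' @return "L1L2FS" or "RLS"
#' @export
setGeneric("technique", function(object) standardGeneric("technique"))

#' @rdname technique
#' @export
setMethod("technique", "TermSubset", function(object) object@technique)
#' @rdname technique
#' @export
setMethod("technique", "SelectionResult", function(object) object@technique)

#' Expression values of a term subset
#' @param object a [TermSubset-class]
#' @return numeric matrix, probesets x samples
#' @export
setGeneric("subsetValues", function(object) standardGeneric("subsetValues"))
#' @rdname subsetValues
#' @export
setMethod("subsetValues", "TermSubset", function(object) object@values)

#' Forward map term -> probesets
#' @param object a [TermProbesetMap-class]
#' @return named list of character vectors
#' @export
setGeneric("termToProbesets", function(object) standardGeneric("termToProbesets"))
#' @rdname termToProbesets
#' @export
setMethod("termToProbesets", "TermProbesetMap", function(object) object@term2probeset)

#' Reverse map probeset -> terms
#' @param object a [TermProbesetMap-class]
#' @return named list of character vectors
#' @export
setGeneric("probesetToTerms", function(object) standardGeneric("probesetToTerms"))
#' @rdname probesetToTerms
#' @export
setMethod("probesetToTerms", "TermProbesetMap", function(object) object@probeset2term)

#' GO domain of an object
#' @param object a [TermProbesetMap-class]
#' @return "MF", "BP" or "CC"
#' @export
setGeneric("goDomain", function(object) standardGeneric("goDomain"))
#' @rdname goDomain
#' @export
setMethod("goDomain", "TermProbesetMap", function(object) object@domain)

#' Resolution table of a probeset/gene map
#' @param object a [ProbesetGeneMap-class]
#' @return data.frame with one row per probeset
#' @export
setGeneric("geneMap", function(object) standardGeneric("geneMap"))
#' @rdname geneMap
#' @export
setMethod("geneMap", "ProbesetGeneMap", function(object) object@map)

#' Per-mu entries of a selection result
#'
#' @param object a [SelectionResult-class]
#' @param mu mu key ("mu1", ..., or "RLS"); NULL returns the full list
#' @return list of per-mu records (or a single record when `mu` is given)
#' @export
setGeneric("perMu", function(object, mu = NULL) standardGeneric("perMu"))
#' @rdname perMu
#' @export
setMethod("perMu", "SelectionResult", function(object, mu = NULL) {
  if (is.null(mu)) return(object@perMu)
  if (!mu %in% names(object@perMu))
    stop("no entry for mu key '", mu, "' in result for ", object@termId)
  object@perMu[[mu]]
})

#' Outer-fold selection frequencies
#' @param object a [SelectionResult-class]
#' @param mu mu key
#' @return named integer vector over the subset's probesets
#' @export
setGeneric("selectionFrequencies",
           function(object, mu) standardGeneric("selectionFrequencies"))
#' @rdname selectionFrequencies
#' @export
setMethod("selectionFrequencies", "SelectionResult",
  function(object, mu) perMu(object, mu)$frequencies)

#' Mean outer-fold test error
#' @param object a [SelectionResult-class]
#' @param mu mu key
#' @return numeric scalar in [0, 1]
#' @export
setGeneric("meanTestError", function(object, mu) standardGeneric("meanTestError"))
#' @rdname meanTestError
#' @export
setMethod("meanTestError", "SelectionResult",
  function(object, mu) perMu(object, mu)$mean_test_error)
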