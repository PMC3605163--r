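# Postprocessing: significance calls, properly-selected variables, unified
# term lists with MCC, histograms and error statistics.

#' Call significant GO terms
#'
#' A term is significant for a given mu key (or for RLS) when its mean
#' outer-fold test error lies strictly below the threshold; an error equal
#' to the threshold fails.
#'
#' @param results named list of [SelectionResult-class]
#' @param errorThreshold error threshold in (0, 0.5]; default 0.30
#' @return data.frame with one row per (term, mu key): term_id, source,
#'   technique, error_estimate, threshold_used, significant
#' @export
callSignificance <- function(results, errorThreshold = 0.30) {
  stopifnot(errorThreshold > 0, errorThreshold <= 0.5)
  rows <- list()
  for (res in results) {
    for (key in names(perMu(res))) {
      err <- meanTestError(res, key)
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = termId(res), source = key, technique = technique(res),
        error_estimate = err, threshold_used = errorThreshold,
        significant = err < errorThreshold, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$term_id, out$source), , drop = FALSE]
}

#' Properly selected variables of a significant term
#'
#' For l1l2-selected terms, a variable is properly selected when its
#' outer-fold selection frequency, as a fraction of the outer fold count,
#' lies strictly above the frequency threshold.  For RLS terms all subset
#' variables are properly selected.
#'
#' @param result a [SelectionResult-class]
#' @param muKey mu key of the verdict ("mu1", ... or "RLS")
#' @param significant logical verdict for this (term, mu); calling on a
#'   non-significant term is a contract error
#' @param freqThreshold frequency threshold as a fraction of outerK
#' @return character vector of probeset ids
#' @export
selectVariables <- function(result, muKey, significant,
                            freqThreshold = 0.5) {
  if (!isTRUE(significant))
    stop("selectVariables called on a non-significant term: ",
         termId(result))
  if (technique(result) == "RLS") return(result@probesetIds)
  freq <- selectionFrequencies(result, muKey)
  names(freq)[freq / result@outerK > freqThreshold]
}

#' Matthews correlation coefficient
#'
#' @param confusion numeric vector or list with elements TP, TN, FP, FN
#' @return MCC in [-1, 1]; any zero factor in the denominator yields 0
#' @export
computeMCC <- function(confusion) {
  tp <- as.numeric(confusion[["TP"]]); tn <- as.numeric(confusion[["TN"]])
  fp <- as.numeric(confusion[["FP"]]); fn <- as.numeric(confusion[["FN"]])
  stopifnot(tp + tn + fp + fn > 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Sum confusion counts over outer splits of one per-mu entry.
confusionTotals <- function(entry) {
  tot <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (s in entry$splits) tot <- tot + s$confusion
  tot
}

#' Build the unified term list for one mu value
#'
#' Merges the significant l1l2 terms at a given mu with the significant
#' RLS terms into one list, the framework's main output: term id and name,
#' subset size, number of properly selected variables, the error estimate
#' used for the significance call, pooled outer-fold confusion counts and
#' the corresponding MCC.  Records are sorted by error estimate (ties by
#' term id).  The two sources are disjoint by routing; overlap is a
#' contract error.
#'
#' @param results named list of [SelectionResult-class]
#' @param verdicts data.frame from [callSignificance()]
#' @param muKey l1l2 mu key to merge with the RLS list
#' @param dag optional [GODag-class] supplying term names
#' @param freqThreshold passed to [selectVariables()]
#' @return data.frame of unified records (possibly zero rows)
#' @export
buildUnifiedList <- function(results, verdicts, muKey, dag = NULL,
                             freqThreshold = 0.5) {
  sig <- verdicts[verdicts$significant &
                  verdicts$source %in% c(muKey, "RLS"), , drop = FALSE]
  if (anyDuplicated(sig$term_id))
    stop("term present in both l1l2 and RLS sources: ",
         sig$term_id[duplicated(sig$term_id)][1L])
  nameOf <- function(t) {
    if (is.null(dag)) return(t)
    tm <- goTerms(dag)
    hit <- tm$name[tm$id == t]
    if (length(hit)) hit[1L] else t
  }
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    res <- results[[sig$term_id[i]]]
    entry <- perMu(res, sig$source[i])
    tot <- confusionTotals(entry)
    sel <- selectVariables(res, sig$source[i], TRUE, freqThreshold)
    data.frame(term_id = sig$term_id[i], term_name = nameOf(sig$term_id[i]),
               total_variables = length(res@probesetIds),
               n_properly_selected = length(sel),
               error_estimate = sig$error_estimate[i],
               TP = tot[["TP"]], TN = tot[["TN"]], FP = tot[["FP"]],
               FN = tot[["FN"]], mcc = computeMCC(tot),
               source = sig$source[i], stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(term_id = character(), term_name = character(),
                    total_variables = integer(),
                    n_properly_selected = integer(),
                    error_estimate = numeric(), TP = numeric(),
                    TN = numeric(), FP = numeric(), FN = numeric(),
                    mcc = numeric(), source = character(),
                    stringsAsFactors = FALSE)
  out[order(out$error_estimate, out$term_id), , drop = FALSE]
}

#' Annotate probesets back to biology
#'
#' Each variable is annotated with its HGNC-verified gene symbol and, when
#' present, Entrez Gene and GenBank ids (external ids may be missing).
#' Unknown probesets yield an unresolved record with a warning.
#'
#' @param ids probeset ids
#' @param p2g a [ProbesetGeneMap-class]
#' @param frequencies optional named frequency vector (l1l2 terms only;
#'   omitted for RLS)
#' @return data.frame: probeset_id, gene_symbol, status, entrez_id,
#'   genbank_id and optionally frequency
#' @export
annotateVariables <- function(ids, p2g, frequencies = NULL) {
  map <- geneMap(p2g)
  idx <- match(ids, map$probeset_id)
  if (anyNA(idx))
    warning("probeset(s) absent from annotation: ",
            paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- data.frame(
    probeset_id = ids,
    gene_symbol = ifelse(is.na(idx), NA_character_,
                         map$resolved_symbol[idx]),
    status = ifelse(is.na(idx), "unresolved", map$status[idx]),
    entrez_id = ifelse(is.na(idx), NA_character_, map$entrez_id[idx]),
    genbank_id = ifelse(is.na(idx), NA_character_, map$genbank_id[idx]),
    stringsAsFactors = FALSE)
  if (!is.null(frequencies))
    out$frequency <- unname(frequencies[ids])
  out
}

#' Selected / not-selected variable histograms
#'
#' For every variable of the expression matrix, counts in how many
#' significant-term subsets it was properly selected, and in how many it
#' was present but not properly selected.  Counting is restricted to
#' significant subsets, so for every variable
#' selected + not-selected = number of significant subsets containing it.
#' For l1l2 one histogram pair exists per mu; RLS yields only the selected
#' histogram (all variables of a significant RLS term are selected).
#'
#' @param results named list of [SelectionResult-class]
#' @param verdicts data.frame from [callSignificance()]
#' @param muKey "mu1", ... or "RLS"
#' @param allProbesets every variable of the expression matrix
#' @param nDomainTerms number of GO terms in the analyzed domain
#' @param freqThreshold passed to [selectVariables()]
#' @param p2g optional [ProbesetGeneMap-class] for gene symbols
#' @return list with data.frames `selected`, `not_selected` (NULL for
#'   RLS) and a `meta` list (total entries, significant terms, domain
#'   terms); variables contained in no significant subset appear in
#'   neither histogram
#' @export
buildHistograms <- function(results, verdicts, muKey, allProbesets,
                            nDomainTerms, freqThreshold = 0.5,
                            p2g = NULL) {
  sig <- verdicts[verdicts$significant & verdicts$source == muKey, ,
                  drop = FALSE]
  selCount <- setNames(integer(length(allProbesets)), allProbesets)
  notCount <- selCount
  for (t in sig$term_id) {
    res <- results[[t]]
    members <- res@probesetIds
    sel <- selectVariables(res, muKey, TRUE, freqThreshold)
    selCount[sel] <- selCount[sel] + 1L
    rest <- setdiff(members, sel)
    notCount[rest] <- notCount[rest] + 1L
  }
  symbolOf <- function(ids) {
    if (is.null(p2g)) return(rep(NA_character_, length(ids)))
    map <- geneMap(p2g)
    map$resolved_symbol[match(ids, map$probeset_id)]
  }
  mkDf <- function(cnt) {
    keep <- names(cnt)[cnt > 0L]
    df <- data.frame(probeset_id = keep, gene_symbol = symbolOf(keep),
                     count = unname(cnt[keep]), stringsAsFactors = FALSE)
    df[order(-df$count, df$probeset_id), , drop = FALSE]
  }
  selected <- mkDf(selCount)
  notSelected <- if (muKey == "RLS") NULL else mkDf(notCount)
  list(selected = selected, not_selected = notSelected,
       meta = list(total_entries = nrow(selected),
                   n_significant_terms = nrow(sig),
                   n_domain_terms = nDomainTerms))
}

#' Classification-error statistics across subsets
#'
#' @param results named list of [SelectionResult-class]
#' @return list with `per_mu` (mean/sd/median of the per-term error
#'   estimates for each mu key) and `per_term` (per-term mean/sd train
#'   error and mean/sd/median test error)
#' @export
summarizeErrors <- function(results) {
  stopifnot(length(results) >= 1L)
  perTerm <- list(); keys <- character()
  for (res in results) {
    for (key in names(perMu(res))) {
      e <- perMu(res, key)
      keys <- union(keys, key)
      perTerm[[length(perTerm) + 1L]] <- data.frame(
        term_id = termId(res), source = key,
        mean_test_error = e$mean_test_error,
        sd_test_error = e$sd_test_error,
        median_test_error = e$median_test_error,
        mean_train_error = e$mean_train_error,
        sd_train_error = e$sd_train_error, stringsAsFactors = FALSE)
    }
  }
  perTerm <- do.call(rbind, perTerm)
  perTerm <- perTerm[order(perTerm$term_id, perTerm$source), , drop = FALSE]
  perMuStats <- do.call(rbind, lapply(sort(keys), function(key) {
    e <- perTerm$mean_test_error[perTerm$source == key]
    data.frame(source = key, n_terms = length(e), mean_error = mean(e),
               sd_error = if (length(e) > 1L) sd(e) else 0,
               median_error = median(e), stringsAsFactors = FALSE)
  }))
  list(per_mu = perMuStats, per_term = perTerm)
}
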