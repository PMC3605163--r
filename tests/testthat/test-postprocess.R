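conf <- function(tp, tn, fp, fn) c(TP = tp, TN = tn, FP = fp, FN = fn)

# two handmade results: one l1l2 term, one RLS term
l1l2Res <- fakeResult("GO:L1", "L1L2FS", paste0("p", 1:4), 4L,
                      testErrors = c(0.2, 0.2, 0.4, 0.2),
                      confusions = list(conf(4, 4, 1, 1), conf(4, 4, 1, 1),
                                        conf(3, 3, 2, 2), conf(4, 4, 1, 1)),
                      selectedPerSplit = list(c("p1", "p2"), c("p1"),
                                              c("p1", "p3"), c("p1", "p2")))
rlsRes <- fakeResult("GO:R1", "RLS", paste0("q", 1:3), 4L,
                     testErrors = c(0.1, 0.1, 0.1, 0.1),
                     confusions = rep(list(conf(5, 4, 1, 0)), 4),
                     selectedPerSplit = rep(list(paste0("q", 1:3)), 4))
results <- list(`GO:L1` = l1l2Res, `GO:R1` = rlsRes)

test_that("significance uses a strict threshold", {
  r <- list(
    a = fakeResult("a", "RLS", "p1", 4L, rep(0.25, 4),
                   rep(list(conf(4, 4, 1, 1)), 4), rep(list("p1"), 4)),
    b = fakeResult("b", "RLS", "p1", 4L, rep(0.30, 4),
                   rep(list(conf(4, 3, 2, 1)), 4), rep(list("p1"), 4)),
    c = fakeResult("c", "RLS", "p1", 4L, rep(0.55, 4),
                   rep(list(conf(2, 2, 3, 3)), 4), rep(list("p1"), 4)))
  v <- callSignificance(r, errorThreshold = 0.30)
  expect_equal(setNames(v$significant, v$term_id),
               c(a = TRUE, b = FALSE, c = FALSE))
  expect_true(all(v$significant == (v$error_estimate < v$threshold_used)))
})

test_that("properly selected variables obey the strict frequency rule", {
  # frequencies in l1l2Res: p1 = 4, p2 = 2, p3 = 1, p4 = 0
  expect_equal(selectVariables(l1l2Res, "mu1", TRUE, freqThreshold = 0.5),
               c("p1"))
  expect_setequal(selectVariables(l1l2Res, "mu1", TRUE,
                                  freqThreshold = 0.4),
                  c("p1", "p2"))
  # threshold 1.0: strictly above never holds, even for frequency = K
  expect_length(selectVariables(l1l2Res, "mu1", TRUE, freqThreshold = 1.0),
                0L)
  # RLS: all subset variables
  expect_equal(selectVariables(rlsRes, "RLS", TRUE), paste0("q", 1:3))
  expect_error(selectVariables(l1l2Res, "mu1", FALSE), "non-significant")
})

test_that("MCC matches the closed form with the zero-denominator rule", {
  expect_equal(computeMCC(conf(5, 5, 0, 0)), 1)
  expect_equal(computeMCC(conf(0, 0, 5, 5)), -1)
  # direct evaluation: (3*4 - 1*2) / sqrt(4*5*5*6)
  expect_equal(computeMCC(conf(3, 4, 1, 2)), 10 / sqrt(600))
  expect_equal(computeMCC(conf(0, 5, 0, 5)), 0)  # zero factor -> 0
})

test_that("unified lists merge disjoint sources, sorted by error", {
  v <- callSignificance(results, errorThreshold = 0.30)
  uni <- buildUnifiedList(results, v, "mu1")
  expect_equal(nrow(uni), 2L)
  expect_equal(uni$term_id, c("GO:R1", "GO:L1"))  # 0.1 before 0.25
  # mcc recomputable from the stored confusion totals
  for (i in seq_len(nrow(uni)))
    expect_equal(uni$mcc[i],
                 computeMCC(conf(uni$TP[i], uni$TN[i], uni$FP[i],
                                 uni$FN[i])))
  expect_equal(uni$n_properly_selected[uni$term_id == "GO:R1"], 3L)
  expect_equal(uni$total_variables[uni$term_id == "GO:L1"], 4L)

  # zero significant terms: empty frame with full header
  vNone <- callSignificance(results, errorThreshold = 0.05)
  uniNone <- buildUnifiedList(results, vNone, "mu1")
  expect_equal(nrow(uniNone), 0L)
  expect_true(all(c("term_id", "mcc", "source") %in% names(uniNone)))
})

test_that("variable annotation tolerates missing external ids", {
  hgnc <- data.frame(approved_symbol = c("AAA", "BBB"),
                     status = "approved", stringsAsFactors = FALSE)
  hgnc$previous_symbols <- list(character(), character())
  hgnc$aliases <- list(character(), character())
  anno <- data.frame(probeset_id = c("p1", "p2"),
                     gene_symbol = c("AAA", "BBB"),
                     entrez_id = c("100", NA),
                     genbank_id = c("NM_1", NA), stringsAsFactors = FALSE)
  anno$go_ids <- list(character(), character())
  p2g <- buildProbesetToGene(anno, hgnc)
  rec <- annotateVariables(c("p1", "p2"), p2g,
                           frequencies = c(p1 = 4L, p2 = 1L))
  expect_equal(rec$gene_symbol, c("AAA", "BBB"))
  expect_true(is.na(rec$entrez_id[2]) && is.na(rec$genbank_id[2]))
  expect_equal(rec$frequency, c(4L, 1L))
  expect_warning(rec2 <- annotateVariables("p9", p2g), "absent")
  expect_equal(rec2$status, "unresolved")
})

test_that("histograms conserve counts over significant subsets", {
  v <- callSignificance(results, errorThreshold = 0.30)
  allPs <- c(paste0("p", 1:4), paste0("q", 1:3), "z1")
  h <- buildHistograms(results, v, "mu1", allPs, nDomainTerms = 10L,
                       freqThreshold = 0.5)
  # GO:L1 (the only mu1-significant term): p1 selected, p2-p4 not
  expect_equal(h$selected$probeset_id, "p1")
  expect_setequal(h$not_selected$probeset_id, c("p2", "p3", "p4"))
  # conservation: selected + not-selected = membership in sig subsets
  for (ps in paste0("p", 1:4)) {
    selc <- h$selected$count[h$selected$probeset_id == ps]
    notc <- h$not_selected$count[h$not_selected$probeset_id == ps]
    expect_equal(sum(selc, notc), 1L)
  }
  # a variable in no significant subset appears in neither histogram
  expect_false("z1" %in% c(h$selected$probeset_id,
                           h$not_selected$probeset_id))
  expect_equal(h$meta$n_significant_terms, 1L)
  expect_equal(h$meta$n_domain_terms, 10L)
  # RLS histogram: selected only
  hr <- buildHistograms(results, v, "RLS", allPs, nDomainTerms = 10L)
  expect_null(hr$not_selected)
  expect_setequal(hr$selected$probeset_id, paste0("q", 1:3))
})

test_that("error statistics match direct recomputation", {
  stats <- summarizeErrors(results)
  mu1 <- stats$per_mu[stats$per_mu$source == "mu1", ]
  expect_equal(mu1$mean_error, 0.25)
  expect_equal(mu1$sd_error, 0)           # single term for mu1
  rls <- stats$per_mu[stats$per_mu$source == "RLS", ]
  expect_equal(rls$median_error, 0.1)
  pt <- stats$per_term[stats$per_term$term_id == "GO:L1", ]
  expect_equal(pt$mean_test_error, 0.25)
  expect_equal(pt$median_test_error, 0.2)
  expect_equal(pt$sd_test_error, sd(c(0.2, 0.2, 0.4, 0.2)))
})
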