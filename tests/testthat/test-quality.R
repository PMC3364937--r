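closureOf <- function(gene, term, graph, negated = FALSE,
                      evidence = "IEA") {
  buildClosure(annotationCorpus(gene = gene, term = term, negated = negated,
                                evidence = evidence,
                                reference = if (all(evidence == "IEA"))
                                  "GO_REF:0000002" else "PMID:1"),
               graph)
}
emptyClosure <- function(graph) {
  closureOf(character(), character(), graph)
}
clsOf <- function(cls, gene, term) {
  cls$classification[cls$gene == gene & cls$term == term]
}

test_that("a new experimental descendant confirms all implied ancestors", {
  g <- chainGraph()
  oldEval <- closureOf("g", B_, g)
  newEval <- closureOf("g", B_, g)
  newRef <- closureOf("g", B_, g, evidence = "IDA")
  cls <- classifyPairs(oldEval, newEval, newRef, g)
  expect_setequal(cls$classification, "confirmed")
  expect_equal(nrow(cls), 3L)
})

test_that("a less specific experimental annotation confirms only its subset", {
  g <- chainGraph()
  oldEval <- closureOf("g", B_, g)
  newEval <- closureOf("g", B_, g)          # electronic B retained
  newRef <- closureOf("g", A_, g, evidence = "IDA")
  cls <- classifyPairs(oldEval, newEval, newRef, g)
  expect_identical(clsOf(cls, "g", A_), "confirmed")
  expect_identical(clsOf(cls, "g", R_), "confirmed")
  expect_identical(clsOf(cls, "g", B_), "uninformative")
})

test_that("disappearance from the new release is implicit rejection", {
  g <- chainGraph()
  oldEval <- closureOf("g", B_, g)
  cls <- classifyPairs(oldEval, emptyClosure(g), emptyClosure(g), g)
  expect_setequal(cls$classification, "removed")
  expect_equal(nrow(cls), 3L)
})

test_that("specialization to a descendant is never counted as removal", {
  g <- chainGraph()
  oldEval <- closureOf("g", A_, g)
  newEval <- closureOf("g", B_, g)          # replaced by descendant
  cls <- classifyPairs(oldEval, newEval, emptyClosure(g), g)
  expect_false(any(cls$classification == "removed"))
  expect_setequal(cls$classification, "uninformative")
})

test_that("NOT qualifiers reject the exact term only, never ancestors", {
  g <- chainGraph()
  oldEval <- closureOf("g", B_, g)
  newEval <- closureOf("g", B_, g)
  newRef <- closureOf("g", B_, g, negated = TRUE, evidence = "IDA")
  cls <- classifyPairs(oldEval, newEval, newRef, g)
  expect_identical(clsOf(cls, "g", B_), "rejected_explicit")
  expect_identical(clsOf(cls, "g", A_), "uninformative")
  expect_identical(clsOf(cls, "g", R_), "uninformative")
})

test_that("an exact-term NOT outranks a simultaneous descendant confirmation", {
  g <- chainGraph()
  oldEval <- closureOf("g", A_, g)
  newEval <- closureOf("g", A_, g)
  # new experimental B (confirms A by inheritance) and NOT at A itself
  newRef <- closureOf(c("g", "g"), c(B_, A_), g, negated = c(FALSE, TRUE),
                      evidence = "IDA")
  cls <- classifyPairs(oldEval, newEval, newRef, g)
  expect_identical(clsOf(cls, "g", A_), "rejected_explicit")
  expect_identical(clsOf(cls, "g", R_), "confirmed")
})

test_that("the worked release pair yields the enumerated per-term counts", {
  fx <- workedFixture()
  ev <- suppressWarnings(
    evaluateReleasePair(fx$old, fx$new, fx$graph,
                        config = evaluationConfig(1, 1), verbose = FALSE))
  tq <- termQuality(ev)
  a <- tq[tq$term == A_, ]
  expect_equal(a$n_confirmed, 1L)
  expect_equal(a$n_rejected_explicit, 1L)
  expect_equal(a$n_removed, 1L)
  expect_equal(a$reliability, 1 / 3)
  b <- tq[tq$term == B_, ]
  expect_equal(b$n_confirmed, 1L)
  expect_equal(b$n_removed, 1L)
  expect_equal(b$reliability, 0.5)
})

test_that("coverage labels new experimental pairs predicted or missed", {
  g <- starGraph()   # B and C siblings under A
  oldEval <- closureOf("g", C_, g)
  oldRef <- emptyClosure(g)
  newRef <- closureOf("g", B_, g, evidence = "IDA")
  cov <- coverageByTerm(oldEval, oldRef, newRef)
  expect_equal(cov$n_missed[cov$term == B_], 1L)
  expect_equal(cov$n_predicted[cov$term == B_], 0L)
  expect_equal(cov$n_predicted[cov$term == A_], 1L)
  expect_equal(cov$n_predicted[cov$term == R_], 1L)
  expect_equal(cov$coverage[cov$term == A_], 1.0)

  # electronic closure covering everything: coverage 1 wherever defined
  oldEvalAll <- closureOf("g", B_, g)
  covAll <- coverageByTerm(oldEvalAll, oldRef, newRef)
  expect_true(all(covAll$coverage == 1.0))

  # no electronic annotations at all: coverage 0 wherever defined
  covNone <- coverageByTerm(emptyClosure(g), oldRef, newRef)
  expect_true(all(covNone$coverage == 0))

  # pairs already experimentally implied in the old release are not events
  covOldKnown <- coverageByTerm(oldEval, closureOf("g", B_, g,
                                                   evidence = "IDA"),
                                newRef)
  expect_equal(nrow(covOldKnown), 0L)
})

test_that("per-term reliability counts exclude uninformative pairs", {
  cls <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    term = "GO:0000002",
    classification = c("confirmed", "rejected_explicit", "removed",
                       "uninformative"),
    stringsAsFactors = FALSE)
  rel <- reliabilityByTerm(cls)
  expect_equal(rel$reliability, 1 / 3)
  expect_equal(rel$n_uninformative, 1L)

  allUninf <- data.frame(gene = "g", term = "GO:0000002",
                         classification = "uninformative",
                         stringsAsFactors = FALSE)
  relU <- reliabilityByTerm(allUninf)
  expect_true(is.na(relU$reliability))   # undefined, never 0 or 1
})

test_that("identical releases are entirely uninformative", {
  fx <- workedFixture()
  expect_warning(
    ev <- evaluateReleasePair(fx$old, fx$old, fx$graph,
                              config = evaluationConfig(1, 1),
                              verbose = FALSE),
    "threshold")
  tq <- termQuality(ev)
  expect_true(all(tq$n_confirmed + tq$n_rejected_explicit +
                    tq$n_removed == 0L))
  expect_equal(nrow(reportable(ev)), 0L)
})

test_that("reporting thresholds flag low-count terms", {
  fx <- workedFixture()
  expect_warning(
    ev <- evaluateReleasePair(fx$old, fx$new, fx$graph,
                              config = evaluationConfig(10, 10),
                              verbose = FALSE),
    "threshold")
  expect_equal(nrow(reportable(ev)), 0L)
  # full table still carries every evaluated term
  expect_gt(nrow(termQuality(ev)), 0L)
})

test_that("closures from different ontologies are refused", {
  g1 <- chainGraph(); g2 <- starGraph()
  a <- closureOf("g", B_, g1)
  b <- closureOf("g", B_, g2)
  expect_error(classifyPairs(a, b, b, g1), "different ontologies")
})

test_that("every old closure pair receives exactly one label", {
  for (seed in 201:220) {
    inst <- randomInstance(seed)
    cl <- instanceClosures(inst)
    cls <- classifyPairs(cl$oldEval, cl$newEval, cl$newRefNew, inst$graph)
    expect_equal(nrow(cls), nrow(positivePairs(cl$oldEval)))
    expect_true(all(cls$classification %in%
                      c("confirmed", "rejected_explicit", "removed",
                        "uninformative")))
  }
})

test_that("classification and coverage match the literal-rule oracle", {
  for (seed in 221:250) {
    inst <- randomInstance(seed)
    cl <- instanceClosures(inst)
    cls <- classifyPairs(cl$oldEval, cl$newEval, cl$newRefNew, inst$graph)
    cls <- cls[order(cls$gene, cls$term), ]

    strat <- function(corpus, cat)
      records(filterCorpus(corpus, categories = cat))[
        , c("gene", "term", "negated")]
    want <- oracleClassify(strat(inst$old, "electronic"),
                           strat(inst$new, "electronic"),
                           strat(inst$old, "experimental"),
                           strat(inst$new, "experimental"), inst$graph)
    expect_equal(cls, want, ignore_attr = TRUE)

    cov <- coverageByTerm(cl$oldEval, cl$oldRef, cl$newRef)
    wantCov <- oracleCoverage(strat(inst$old, "electronic"),
                              strat(inst$old, "experimental"),
                              strat(inst$new, "experimental"), inst$graph)
    wantAgg <- stats::aggregate(predicted ~ term, wantCov,
                                function(v) c(sum(v), sum(!v)))
    for (i in seq_len(nrow(wantAgg))) {
      row <- cov[cov$term == wantAgg$term[[i]], ]
      expect_equal(row$n_predicted, wantAgg$predicted[i, 1])
      expect_equal(row$n_missed, wantAgg$predicted[i, 2])
    }
    expect_setequal(cov$term, wantAgg$term)
  }
})

test_that("reliability is monotone under added confirmations and removals", {
  base <- data.frame(gene = paste0("g", 1:4), term = "GO:0000002",
                     classification = c("confirmed", "removed",
                                        "uninformative", "confirmed"),
                     stringsAsFactors = FALSE)
  r0 <- reliabilityByTerm(base)$reliability
  plusConf <- rbind(base, data.frame(gene = "g9", term = "GO:0000002",
                                     classification = "confirmed"))
  expect_gte(reliabilityByTerm(plusConf)$reliability, r0)
  plusRem <- rbind(base, data.frame(gene = "g9", term = "GO:0000002",
                                    classification = "removed"))
  expect_lte(reliabilityByTerm(plusRem)$reliability, r0)
})
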