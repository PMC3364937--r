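# Release differencing: classification of closure pairs, per-term
# reliability and coverage, and the full evaluation pipeline.

.pairKey <- function(gene, term) paste(gene, term, sep = "\r")

#' Classify old-release closure pairs against the new release
#'
#' The accounting unit is the closure (gene, term) pair. Every pair of the
#' old evaluated stratum's closure receives exactly one label:
#'
#' * `rejected_explicit` — the new reference (experimental) release
#'   asserts NOT on exactly this term for this gene. NOT never propagates.
#' * `confirmed` — otherwise, if the term is in the gene's new reference
#'   closure: a new experimental annotation to the term or any descendant
#'   implies it, and a less specific new experimental annotation confirms
#'   exactly the ancestral subset it implies, leaving deeper pairs
#'   unlabeled here.
#' * `removed` — otherwise, if the pair has left the new evaluated
#'   stratum's closure (implicit rejection). Because membership is tested
#'   on the closure, an annotation replaced by a more specific descendant
#'   is still implied and is not considered removed.
#' * `uninformative` — otherwise (unchanged).
#'
#' The explicit curator contradiction takes precedence over a simultaneous
#' descendant confirmation.
#'
#' @param oldEval closure of the evaluated stratum in the old release.
#' @param newEval closure of the evaluated stratum in the new release.
#' @param newRef closure of the reference (experimental) stratum in the
#'   new release, restricted to annotations that are new, i.e. absent from
#'   the old reference closure (see [newReferenceClosure()]).
#' @param graph the [OntologyGraph-class] all closures were built on;
#'   closures built on different ontologies are an error.
#' @return data.frame with columns `gene`, `term`, `classification`.
#' @export
classifyPairs <- function(oldEval, newEval, newRef, graph) {
  .checkSameGraph(graph, oldEval, newEval, newRef)
  op <- oldEval@positive
  k <- .pairKey(op$gene, op$term)
  cls <- rep("uninformative", nrow(op))
  cls[!(k %in% .pairKey(newEval@positive$gene, newEval@positive$term))] <-
    "removed"
  cls[k %in% .pairKey(newRef@positive$gene, newRef@positive$term)] <-
    "confirmed"
  cls[k %in% .pairKey(newRef@negated$gene, newRef@negated$term)] <-
    "rejected_explicit"
  data.frame(gene = op$gene, term = op$term, classification = cls,
             stringsAsFactors = FALSE)
}

.checkSameGraph <- function(graph, ...) {
  want <- sort(graph@terms)
  for (cl in list(...))
    if (!identical(cl@graphTerms, want))
      stop("closures were built on different ontologies")
}

#' Restrict a reference closure to new annotations
#'
#' "New" experimental annotations are those added during the interval:
#' positive closure pairs of the new reference stratum absent from the old
#' reference closure, and NOT pairs absent from the old NOT set. A pair
#' already experimentally implied in the old release confirms nothing and
#' is not a coverage event.
#'
#' @param newRef,oldRef [AnnotationClosure-class] objects of the reference
#'   stratum in the new and old release.
#' @return an [AnnotationClosure-class] of the new pairs only.
#' @export
newReferenceClosure <- function(newRef, oldRef) {
  pos <- newRef@positive
  keep <- !(.pairKey(pos$gene, pos$term) %in%
              .pairKey(oldRef@positive$gene, oldRef@positive$term))
  neg <- newRef@negated
  keepn <- !(.pairKey(neg$gene, neg$term) %in%
               .pairKey(oldRef@negated$gene, oldRef@negated$term))
  new("AnnotationClosure", positive = pos[keep, , drop = FALSE],
      negated = neg[keepn, , drop = FALSE],
      stratum = paste0(newRef@stratum, " (new)"),
      graphTerms = newRef@graphTerms)
}

#' Per-term reliability from pair classifications
#'
#' For every term, counts its confirmed, explicitly rejected and removed
#' closure pairs; reliability is confirmed / (confirmed + rejected +
#' removed). Uninformative pairs do not enter the ratio; a term whose
#' pairs are all uninformative has undefined (`NA`) reliability and is
#' still reported.
#'
#' @param classifications data.frame from [classifyPairs()].
#' @return data.frame with columns `term`, `n_confirmed`,
#'   `n_rejected_explicit`, `n_removed`, `n_uninformative`, `reliability`.
#' @export
reliabilityByTerm <- function(classifications) {
  dt <- as.data.table(classifications)
  out <- dt[, .(n_confirmed = sum(classification == "confirmed"),
                n_rejected_explicit = sum(classification ==
                                            "rejected_explicit"),
                n_removed = sum(classification == "removed"),
                n_uninformative = sum(classification == "uninformative")),
            by = term]
  out[, denom := n_confirmed + n_rejected_explicit + n_removed]
  out[, reliability := ifelse(denom > 0, n_confirmed / denom, NA_real_)]
  out[, denom := NULL]
  setorder(out, term)
  setDF(out)
  out
}

#' Per-term coverage of new experimental annotations
#'
#' Every new experimental closure pair — present in the new reference
#' closure but not implied by the old reference closure — is either
#' predicted (the old evaluated stratum's closure already contained it) or
#' missed. Coverage is predicted / (predicted + missed).
#'
#' @param oldEval closure of the evaluated stratum in the old release.
#' @param oldRef closure of the reference stratum in the old release.
#' @param newRef closure of the reference stratum in the new release
#'   (unrestricted; the new-pair restriction happens here).
#' @return data.frame with columns `term`, `n_predicted`, `n_missed`,
#'   `coverage`.
#' @export
coverageByTerm <- function(oldEval, oldRef, newRef) {
  pos <- newRef@positive
  newp <- pos[!(.pairKey(pos$gene, pos$term) %in%
                  .pairKey(oldRef@positive$gene, oldRef@positive$term)), ,
              drop = FALSE]
  predicted <- .pairKey(newp$gene, newp$term) %in%
    .pairKey(oldEval@positive$gene, oldEval@positive$term)
  dt <- data.table(term = newp$term, predicted = predicted)
  out <- dt[, .(n_predicted = sum(predicted),
                n_missed = sum(!predicted)), by = term]
  out[, coverage := n_predicted / (n_predicted + n_missed)]
  setorder(out, term)
  setDF(out)
  out
}

#' Construct an EvaluationConfig
#'
#' @param minOldAnnotations minimum closure pairs in the old evaluated
#'   stratum for a term to be reportable (default 10).
#' @param minNewExperimental minimum closure pairs in the new reference
#'   stratum for a term to be reportable (default 10).
#' @param evaluatedCategory evidence category evaluated (default
#'   `"electronic"`; use `"curated"` to evaluate curated annotations with
#'   the same pipeline).
#' @param referenceCategory evidence category used to confirm/reject
#'   (default `"experimental"`).
#' @param sources optional electronic-source selector for the evaluated
#'   stratum (e.g. `"interpro"`).
#' @param taxa optional taxon selector applied to all strata.
#' @param namespaces optional namespace selector applied to all strata.
#' @return an [EvaluationConfig-class].
#' @export
evaluationConfig <- function(minOldAnnotations = 10L,
                             minNewExperimental = 10L,
                             evaluatedCategory = "electronic",
                             referenceCategory = "experimental",
                             sources = character(), taxa = integer(),
                             namespaces = character()) {
  new("EvaluationConfig",
      minOldAnnotations = as.integer(minOldAnnotations),
      minNewExperimental = as.integer(minNewExperimental),
      evaluatedCategory = evaluatedCategory,
      referenceCategory = referenceCategory,
      sources = as.character(sources), taxa = as.integer(taxa),
      namespaces = as.character(namespaces))
}

#' Evaluate the quality of one release against a later one
#'
#' The full pipeline: intersect the two ontology releases' term sets,
#' apply qualifier hygiene, stratify both corpora into the evaluated
#' (default electronic) and reference (default experimental) strata,
#' build inheritance closures, classify every old evaluated closure pair
#' (reliability) and every new reference closure pair (coverage), and
#' join per-term specificity computed from the old release's evaluated
#' stratum. Terms below the annotation-count thresholds are retained in
#' the full table and flagged; [reportable()] returns only the rows
#' passing both thresholds.
#'
#' @param oldCorpus,newCorpus the two [AnnotationCorpus-class] releases.
#' @param graphOld the ontology release matching the old corpus.
#' @param graphNew the ontology release matching the new corpus; defaults
#'   to `graphOld` (closures are propagated over this graph).
#' @param config an [EvaluationConfig-class].
#' @param verbose emit pipeline bookkeeping messages (default TRUE).
#' @return a [ReleaseEvaluation-class].
#' @export
evaluateReleasePair <- function(oldCorpus, newCorpus, graphOld,
                                graphNew = graphOld,
                                config = evaluationConfig(),
                                verbose = TRUE) {
  say <- if (verbose) message else function(...) invisible(NULL)
  shared <- sharedTerms(graphOld, graphNew)
  say("shared non-obsolete terms: ", length(shared))

  hyg_old <- dropContradictoryPairs(oldCorpus)
  hyg_new <- dropContradictoryPairs(newCorpus)
  say("contradictory (gene, term) pairs dropped: old=",
      nrow(hyg_old$dropped), " new=", nrow(hyg_new$dropped))

  old <- .restrictToShared(hyg_old$corpus, graphNew, shared)
  newc <- .restrictToShared(hyg_new$corpus, graphNew, shared)
  say("records after shared-term restriction: old=", nrow(old@records),
      " new=", nrow(newc@records))

  selEval <- function(corpus) {
    out <- filterCorpus(corpus, categories = config@evaluatedCategory,
                        sources = if (length(config@sources))
                          config@sources else NULL,
                        taxa = if (length(config@taxa)) config@taxa else NULL,
                        namespaces = if (length(config@namespaces))
                          config@namespaces else NULL,
                        graph = graphNew)
    out
  }
  selRef <- function(corpus) {
    filterCorpus(corpus, categories = config@referenceCategory,
                 taxa = if (length(config@taxa)) config@taxa else NULL,
                 namespaces = if (length(config@namespaces))
                   config@namespaces else NULL,
                 graph = graphNew)
  }
  oldEvalCorpus <- selEval(old); newEvalCorpus <- selEval(newc)
  oldRefCorpus <- selRef(old); newRefCorpus <- selRef(newc)
  say("stratum sizes (records): old ", config@evaluatedCategory, "=",
      nrow(oldEvalCorpus@records), ", old ", config@referenceCategory, "=",
      nrow(oldRefCorpus@records), ", new ", config@evaluatedCategory, "=",
      nrow(newEvalCorpus@records), ", new ", config@referenceCategory, "=",
      nrow(newRefCorpus@records))

  if (!nrow(oldEvalCorpus@records)) {
    warning("evaluated stratum of the old release is empty")
    return(new("ReleaseEvaluation", termQuality = .emptyQuality(),
               config = config,
               log = list(sharedTerms = length(shared))))
  }

  oldEval <- buildClosure(oldEvalCorpus, graphNew, config@evaluatedCategory)
  newEval <- buildClosure(newEvalCorpus, graphNew, config@evaluatedCategory)
  oldRef <- buildClosure(oldRefCorpus, graphNew, config@referenceCategory)
  newRef <- buildClosure(newRefCorpus, graphNew, config@referenceCategory)
  newRefNew <- newReferenceClosure(newRef, oldRef)

  cls <- classifyPairs(oldEval, newEval, newRefNew, graphNew)
  rel <- reliabilityByTerm(cls)
  cov <- coverageByTerm(oldEval, oldRef, newRef)

  n_old <- table(oldEval@positive$term)
  n_new_exp <- table(newRef@positive$term)

  freq <- termFrequency(oldEval, graphNew)
  ic <- informationContent(freq)

  all_terms <- sort(union(rel$term, cov$term))
  tq <- data.frame(term = all_terms, stringsAsFactors = FALSE)
  tq$namespace <- unname(termNamespaces(graphNew)[all_terms])
  tq$name <- unname(termNames(graphNew)[all_terms])
  tq$specificity <- unname(ic[all_terms])
  tq <- merge(tq, rel[, c("term", "n_confirmed", "n_rejected_explicit",
                          "n_removed", "reliability")],
              by = "term", all.x = TRUE)
  tq <- merge(tq, cov, by = "term", all.x = TRUE)
  for (col in c("n_confirmed", "n_rejected_explicit", "n_removed",
                "n_predicted", "n_missed"))
    tq[[col]][is.na(tq[[col]])] <- 0L
  tq$n_old_electronic <- as.integer(n_old[tq$term])
  tq$n_old_electronic[is.na(tq$n_old_electronic)] <- 0L
  tq$n_new_experimental <- as.integer(n_new_exp[tq$term])
  tq$n_new_experimental[is.na(tq$n_new_experimental)] <- 0L
  tq$reportable <- tq$n_old_electronic >= config@minOldAnnotations &
    tq$n_new_experimental >= config@minNewExperimental
  tq <- tq[order(tq$term), , drop = FALSE]
  rownames(tq) <- NULL

  if (!any(tq$reportable))
    warning("no term passes the reporting thresholds (",
            config@minOldAnnotations, "/", config@minNewExperimental, ")")

  new("ReleaseEvaluation", termQuality = tq, config = config,
      log = list(sharedTerms = length(shared),
                 droppedContradictoryOld = nrow(hyg_old$dropped),
                 droppedContradictoryNew = nrow(hyg_new$dropped),
                 oldEvalRecords = nrow(oldEvalCorpus@records),
                 newEvalRecords = nrow(newEvalCorpus@records),
                 oldRefRecords = nrow(oldRefCorpus@records),
                 newRefRecords = nrow(newRefCorpus@records),
                 oldEvalPairs = nrow(oldEval@positive),
                 classifications = table(cls$classification)))
}

.restrictToShared <- function(corpus, graph, shared) {
  rec <- corpus@records
  resolved <- resolveTermIds(graph, rec$term)
  keep <- !is.na(resolved) & resolved %in% shared
  rec <- rec[keep, , drop = FALSE]
  rec$term <- resolved[keep]
  .makeCorpus(rec, corpus@releaseLabel)
}

.emptyQuality <- function() {
  data.frame(term = character(), namespace = character(), name = character(),
             specificity = numeric(), n_confirmed = integer(),
             n_rejected_explicit = integer(), n_removed = integer(),
             reliability = numeric(), n_predicted = integer(),
             n_missed = integer(), coverage = numeric(),
             n_old_electronic = integer(), n_new_experimental = integer(),
             reportable = logical(), stringsAsFactors = FALSE)
}

#' @rdname evaluation-accessors
setMethod("termQuality", "ReleaseEvaluation", function(x) x@termQuality)

#' @rdname evaluation-accessors
setMethod("reportable", "ReleaseEvaluation", function(x) {
  x@termQuality[x@termQuality$reportable, , drop = FALSE]
})

setMethod("show", "ReleaseEvaluation", function(object) {
  tq <- object@termQuality
  cat("ReleaseEvaluation:", nrow(tq), "terms evaluated,",
      sum(tq$reportable), "reportable (thresholds ",
      object@config@minOldAnnotations, "/",
      object@config@minNewExperimental, ")\n")
  rep <- tq[tq$reportable, , drop = FALSE]
  if (nrow(rep)) {
    r <- rep$reliability[!is.na(rep$reliability)]
    v <- rep$coverage[!is.na(rep$coverage)]
    if (length(r)) cat("  median reportable reliability:",
                       signif(stats::median(r), 4), "\n")
    if (length(v)) cat("  median reportable coverage:",
                       signif(stats::median(v), 4), "\n")
  }
})

#' Write a per-term quality table as TSV
#'
#' @param evaluation a [ReleaseEvaluation-class] (or its
#'   [termQuality()] data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTermQuality <- function(evaluation, path) {
  tq <- if (is(evaluation, "ReleaseEvaluation"))
    termQuality(evaluation) else evaluation
  utils::write.table(tq, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
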