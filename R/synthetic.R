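# Seeded synthetic ontologies and release pairs with exported ground
# truth, for validating the evaluation pipeline end to end.

#' Construct a SimulationConfig
#'
#' Defaults describe a mid-sized corpus with event rates giving an
#' expected reliability of 0.5 (confirm / (confirm + reject + remove)),
#' in the range observed for real electronic annotations, and a source
#' mix dominated by domain- and keyword-based pipelines.
#'
#' @param nTerms terms per namespace, including the root.
#' @param maxParents maximum parents per non-root term.
#' @param nGenes genes carrying electronic annotations.
#' @param annotationsPerGene mean electronic annotations per gene in
#'   `[1, 3]`; each gene is annotated in that many distinct namespaces.
#' @param pConfirm,pReject,pRemove,pSpecialize,pUnchanged event
#'   probabilities per electronic annotation; must sum to 1.
#' @param sourceMix named probability vector over the six electronic
#'   source labels.
#' @param nBackground genes with old experimental annotations carried
#'   unchanged into the new release.
#' @param nNovel genes receiving novel new experimental annotations
#'   (pure coverage misses).
#' @param seed integer seed driving the single pseudo-random stream for
#'   both ontology structure and events.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nTerms = 150L, maxParents = 3L, nGenes = 500L,
                             annotationsPerGene = 2,
                             pConfirm = 0.15, pReject = 0.05,
                             pRemove = 0.10, pSpecialize = 0.10,
                             pUnchanged = 0.60,
                             sourceMix = c(interpro = 0.35,
                                           uniprotkb_kw = 0.30,
                                           ensembl_compara = 0.10,
                                           ec2go = 0.10,
                                           uniprot_subcell = 0.10,
                                           hamap2go = 0.05),
                             nBackground = max(1L, round(nGenes / 5)),
                             nNovel = max(1L, round(nGenes / 5)),
                             seed = 1L) {
  new("SimulationConfig", nTerms = as.integer(nTerms),
      maxParents = as.integer(maxParents), nGenes = as.integer(nGenes),
      annotationsPerGene = annotationsPerGene,
      pConfirm = pConfirm, pReject = pReject, pRemove = pRemove,
      pSpecialize = pSpecialize, pUnchanged = pUnchanged,
      sourceMix = sourceMix, nBackground = as.integer(nBackground),
      nNovel = as.integer(nNovel), seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a random rooted ontology
#'
#' One rooted DAG per namespace: terms are created in order and every
#' non-root term draws 1 to `maxParents` parents among earlier terms of
#' the same namespace, which guarantees acyclicity and root reachability.
#' About one edge in ten is `part_of`, the rest `is_a` (both propagate).
#' Deterministic given the seed.
#'
#' @param config a [SimulationConfig-class].
#' @param seed seed to use; defaults to `config@seed`.
#' @return an [OntologyGraph-class].
#' @export
generateOntology <- function(config, seed = config@seed) {
  .withSeed(seed, .genOntology(config))
}

.genOntology <- function(config) {
  nT <- config@nTerms
  terms <- character(); nm <- character(); ns_of <- character()
  e_child <- character(); e_parent <- character(); e_rel <- character()
  for (i in seq_along(.GO_NAMESPACES)) {
    ns <- .GO_NAMESPACES[[i]]
    ids <- sprintf("GO:%07d", (i - 1L) * nT + seq_len(nT))
    terms <- c(terms, ids)
    nm[ids] <- paste0("synthetic ", sub("_", " ", ns), " term ", seq_len(nT))
    nm[ids[1L]] <- paste0(ns, " root")
    ns_of[ids] <- ns
    if (nT > 1L) {
      for (k in 2L:nT) {
        np <- sample.int(min(config@maxParents, k - 1L), 1L)
        pars <- ids[sample.int(k - 1L, np)]
        e_child <- c(e_child, rep(ids[[k]], np))
        e_parent <- c(e_parent, pars)
        e_rel <- c(e_rel, ifelse(runif(np) < 0.9, "is_a", "part_of"))
      }
    }
  }
  obs <- rep(FALSE, length(terms)); names(obs) <- terms
  makeOntologyGraph(terms = terms, name = nm, namespace = ns_of,
                    obsolete = obs,
                    edges = data.frame(child = e_child, parent = e_parent,
                                       relation = e_rel,
                                       stringsAsFactors = FALSE))
}

# Draw, for n genes, which namespaces each is annotated in: a count in
# 1..3 with mean annotationsPerGene (1 + Binomial(2, (mean-1)/2)), then
# that many distinct namespaces uniformly. Returns a data.frame with one
# row per (gene, namespace-index) annotation slot.
.drawAnnotationSlots <- function(genes, meanPerGene) {
  n <- length(genes)
  k <- 1L + rbinom(n, 2L, (meanPerGene - 1) / 2)
  perm <- apply(matrix(runif(3L * n), nrow = 3L), 2L, order)
  nsIdx <- unlist(lapply(seq_len(n), function(i) perm[seq_len(k[[i]]), i]),
                  use.names = FALSE)
  data.frame(gene = rep(genes, k), nsIdx = nsIdx, stringsAsFactors = FALSE)
}

.EVENTS <- c("confirm", "reject", "remove", "specialize", "unchanged")

#' Generate a synthetic release pair with ground truth
#'
#' Builds an ontology, an older release of electronic (IEA) annotations
#' plus a background of experimental annotations, and a newer release in
#' which every electronic annotation independently undergoes one event:
#'
#' * `confirm` — a new experimental annotation appears at the term or at
#'   a random descendant (each with probability one half); the electronic
#'   annotation is kept.
#' * `reject` — a new experimental NOT annotation appears at the exact
#'   term and the contradicted electronic annotation is dropped (as
#'   curation pipelines filter IEA annotations contradicted by a NOT).
#' * `remove` — the electronic annotation silently disappears.
#' * `specialize` — the electronic annotation is replaced by one at a
#'   random proper descendant (falling back to the exact term, tallied
#'   separately, when the term has no descendant).
#' * `unchanged` — carried over verbatim.
#'
#' Novel experimental annotations (coverage misses) are injected on a
#' disjoint gene pool, and background experimental annotations are carried
#' unchanged on another disjoint pool, so reliability and coverage ground
#' truths stay independent. Each gene carries at most one electronic
#' annotation per namespace, so the expected closure-pair tallies are
#' exactly computable from the drawn events: the returned ground truth
#' contains both per-event and per-closure-pair tallies along with the
#' expected pooled reliability `pConfirm / (pConfirm + pReject + pRemove)`
#' and the realized pooled coverage. A single seeded pseudo-random stream
#' drives structure and events; identical seeds give identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `graph` ([OntologyGraph-class]), `old` and
#'   `new` ([AnnotationCorpus-class]) and `truth` (list; see
#'   Details).
#' @export
generateReleasePair <- function(config) {
  .withSeed(config@seed, .genReleasePair(config))
}

.genReleasePair <- function(config) {
  graph <- .genOntology(config)
  ns_list <- lapply(.GO_NAMESPACES, function(ns) {
    live <- termIds(graph)[termNamespaces(graph) == ns]
    root <- names(namespaceRoots(graph))[namespaceRoots(graph) == ns]
    setdiff(live, root)
  })
  ancLen <- lengths(graph@ancestorSets)
  descOf <- graph@descendantSets
  refOf <- c(interpro = "GO_REF:0000002", ec2go = "GO_REF:0000003",
             uniprotkb_kw = "GO_REF:0000004",
             ensembl_compara = "GO_REF:0000019",
             hamap2go = "GO_REF:0000020",
             uniprot_subcell = "GO_REF:0000023")

  ## old electronic annotations -------------------------------------------
  elecGenes <- sprintf("G%06d", seq_len(config@nGenes))
  slots <- .drawAnnotationSlots(elecGenes, config@annotationsPerGene)
  nAnn <- nrow(slots)
  term <- character(nAnn)
  for (i in 1:3) {
    sel <- slots$nsIdx == i
    if (any(sel))
      term[sel] <- ns_list[[i]][sample.int(length(ns_list[[i]]),
                                           sum(sel), replace = TRUE)]
  }
  srcLabel <- sample(names(config@sourceMix), nAnn, replace = TRUE,
                     prob = config@sourceMix)
  elec <- data.frame(gene = slots$gene, term = term,
                     reference = unname(refOf[srcLabel]),
                     stringsAsFactors = FALSE)

  ## background experimental (old, carried over) ---------------------------
  bgGenes <- sprintf("B%06d", seq_len(config@nBackground))
  bgSlots <- .drawAnnotationSlots(bgGenes, config@annotationsPerGene)
  bgTerm <- character(nrow(bgSlots))
  for (i in 1:3) {
    sel <- bgSlots$nsIdx == i
    if (any(sel))
      bgTerm[sel] <- ns_list[[i]][sample.int(length(ns_list[[i]]),
                                             sum(sel), replace = TRUE)]
  }

  ## events ----------------------------------------------------------------
  p <- c(config@pConfirm, config@pReject, config@pRemove,
         config@pSpecialize, config@pUnchanged)
  event <- sample(.EVENTS, nAnn, replace = TRUE, prob = p)

  confirmAt <- rep(NA_character_, nAnn)
  specializeAt <- rep(NA_character_, nAnn)
  fallback <- logical(nAnn)
  for (j in which(event == "confirm")) {
    t <- elec$term[[j]]
    dd <- setdiff(descOf[[t]], t)
    confirmAt[[j]] <- if (length(dd) && runif(1L) < 0.5)
      dd[[sample.int(length(dd), 1L)]] else t
  }
  for (j in which(event == "specialize")) {
    t <- elec$term[[j]]
    dd <- setdiff(descOf[[t]], t)
    if (length(dd)) {
      specializeAt[[j]] <- dd[[sample.int(length(dd), 1L)]]
    } else {
      specializeAt[[j]] <- t
      fallback[[j]] <- TRUE
    }
  }

  ## novel experimental annotations (new release only) ----------------------
  nvGenes <- sprintf("N%06d", seq_len(config@nNovel))
  nvSlots <- .drawAnnotationSlots(nvGenes, config@annotationsPerGene)
  nvTerm <- character(nrow(nvSlots))
  for (i in 1:3) {
    sel <- nvSlots$nsIdx == i
    if (any(sel))
      nvTerm[sel] <- ns_list[[i]][sample.int(length(ns_list[[i]]),
                                             sum(sel), replace = TRUE)]
  }

  ## assemble corpora --------------------------------------------------------
  oldCorpus <- .rbindCorpus(list(
    .elecRecords(elec$gene, elec$term, elec$reference),
    .expRecords(bgSlots$gene, bgTerm)
  ), releaseLabel = "synthetic-old")

  keepElec <- event %in% c("confirm", "unchanged")
  spec <- event == "specialize"
  newCorpus <- .rbindCorpus(list(
    .elecRecords(elec$gene[keepElec], elec$term[keepElec],
                 elec$reference[keepElec]),
    .elecRecords(elec$gene[spec], specializeAt[spec], elec$reference[spec]),
    .expRecords(elec$gene[event == "confirm"],
                confirmAt[event == "confirm"]),
    .expRecords(elec$gene[event == "reject"], elec$term[event == "reject"],
                negated = TRUE),
    .expRecords(bgSlots$gene, bgTerm),
    .expRecords(nvSlots$gene, nvTerm)
  ), releaseLabel = "synthetic-new")

  ## ground truth ------------------------------------------------------------
  tally <- as.list(table(factor(event, levels = .EVENTS)))
  tally <- lapply(tally, as.integer)
  tally$specializeFallback <- as.integer(sum(fallback))

  aLen <- ancLen[elec$term]
  confirmed_pairs <- sum(aLen[event == "confirm"])
  rejected_pairs <- sum(event == "reject")
  removed_pairs <- sum(aLen[event == "remove"]) +
    sum(aLen[event == "reject"] - 1L)
  uninformative_pairs <- sum(aLen[event %in% c("unchanged", "specialize")])

  predicted_pairs <- confirmed_pairs
  missed_pairs <- sum(ancLen[confirmAt[event == "confirm"]] -
                        aLen[event == "confirm"]) +
    sum(ancLen[nvTerm])

  denom <- config@pConfirm + config@pReject + config@pRemove
  nInf <- tally$confirm + tally$reject + tally$remove
  truth <- list(
    config = list(nTerms = config@nTerms, maxParents = config@maxParents,
                  nGenes = config@nGenes,
                  annotationsPerGene = config@annotationsPerGene,
                  pConfirm = config@pConfirm, pReject = config@pReject,
                  pRemove = config@pRemove,
                  pSpecialize = config@pSpecialize,
                  pUnchanged = config@pUnchanged,
                  nBackground = config@nBackground, nNovel = config@nNovel,
                  seed = config@seed),
    nElectronicAnnotations = nAnn,
    eventTallies = tally,
    expectedReliability = if (denom > 0) config@pConfirm / denom else NA,
    realizedReliability = if (nInf > 0)
      tally$confirm / nInf else NA,
    pairTallies = list(confirmed = confirmed_pairs,
                       rejected_explicit = rejected_pairs,
                       removed = removed_pairs,
                       uninformative = uninformative_pairs),
    coveragePairs = list(predicted = predicted_pairs,
                         missed = missed_pairs),
    realizedCoverage = if (predicted_pairs + missed_pairs > 0)
      predicted_pairs / (predicted_pairs + missed_pairs) else NA
  )
  list(graph = graph, old = oldCorpus, new = newCorpus, truth = truth)
}

.elecRecords <- function(gene, term, reference) {
  if (!length(gene)) return(.emptyRecords())
  records(annotationCorpus(gene = gene, term = term, evidence = "IEA",
                           reference = reference, assignedBy = "SIM",
                           date = "20200101"))
}

.expRecords <- function(gene, term, negated = FALSE) {
  if (!length(gene)) return(.emptyRecords())
  records(annotationCorpus(gene = gene, term = term, evidence = "IDA",
                           reference = "PMID:0000001", negated = negated,
                           assignedBy = "SIM", date = "20230101"))
}

.rbindCorpus <- function(recordList, releaseLabel) {
  rec <- do.call(rbind, recordList)
  rownames(rec) <- NULL
  .makeCorpus(rec, releaseLabel)
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of [generateReleasePair()]'s result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
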