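# Shared fixtures, all built in code.

# chain R <- A <- B (biological_process)
chainGraph <- function() {
  terms <- c("GO:0000001", "GO:0000002", "GO:0000003")
  names(terms) <- NULL
  nm <- setNames(c("R", "A", "B"), terms)
  ns <- setNames(rep("biological_process", 3), terms)
  obs <- setNames(rep(FALSE, 3), terms)
  makeOntologyGraph(terms, nm, ns, obs,
                    edges = data.frame(
                      child = c("GO:0000002", "GO:0000003"),
                      parent = c("GO:0000001", "GO:0000002"),
                      relation = "is_a", stringsAsFactors = FALSE))
}

# diamond: R <- A <- B and R <- C <- B
diamondGraph <- function() {
  terms <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004")
  nm <- setNames(c("R", "A", "C", "B"), terms)
  ns <- setNames(rep("biological_process", 4), terms)
  obs <- setNames(rep(FALSE, 4), terms)
  makeOntologyGraph(terms, nm, ns, obs,
                    edges = data.frame(
                      child = c("GO:0000002", "GO:0000003",
                                "GO:0000004", "GO:0000004"),
                      parent = c("GO:0000001", "GO:0000001",
                                 "GO:0000002", "GO:0000003"),
                      relation = "is_a", stringsAsFactors = FALSE))
}

# star: R <- A; A <- B; A <- C  (B, C siblings under A)
starGraph <- function() {
  terms <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004")
  nm <- setNames(c("R", "A", "B", "C"), terms)
  ns <- setNames(rep("biological_process", 4), terms)
  obs <- setNames(rep(FALSE, 4), terms)
  makeOntologyGraph(terms, nm, ns, obs,
                    edges = data.frame(
                      child = c("GO:0000002", "GO:0000003", "GO:0000004"),
                      parent = c("GO:0000001", "GO:0000002", "GO:0000002"),
                      relation = "is_a", stringsAsFactors = FALSE))
}

R_ <- "GO:0000001"; A_ <- "GO:0000002"; B_ <- "GO:0000003"; C_ <- "GO:0000004"

# Bind several corpora (same release) into one.
bindCorpora <- function(..., releaseLabel = "fixture") {
  recs <- lapply(list(...), records)
  GOAnnoQC:::.rbindCorpus(recs, releaseLabel)
}

# The hand-enumerated release pair on starGraph:
# old electronic: g1 -> B, g2 -> A, g3 -> B
# new: electronic g1 -> B kept; experimental g1 -> B; experimental NOT
# g2 -> A (electronic for g2 dropped); g3 absent entirely.
workedFixture <- function() {
  g <- starGraph()
  old <- annotationCorpus(gene = c("g1", "g2", "g3"),
                          term = c(B_, A_, B_),
                          releaseLabel = "fixture-old")
  newc <- bindCorpora(
    annotationCorpus(gene = "g1", term = B_),
    annotationCorpus(gene = c("g1", "g2"), term = c(B_, A_),
                     evidence = "IDA", reference = "PMID:1",
                     negated = c(FALSE, TRUE)),
    releaseLabel = "fixture-new")
  list(graph = g, old = old, new = newc)
}

# Random instance for oracle-equivalence checks: a small random ontology
# plus arbitrary (not event-model) old/new corpora exercising every rule
# path, hygiene-filtered and stratified the way the pipeline expects.
randomInstance <- function(seed, maxTerms = 15L, maxGenes = 30L) {
  set.seed(seed)
  nT <- sample(3:maxTerms, 1L)
  g <- generateOntology(simulationConfig(nTerms = nT, maxParents = 2L),
                        seed = seed + 100000L)
  live <- termIds(g)
  genes <- paste0("g", seq_len(sample(5:maxGenes, 1L)))

  rpairs <- function(p, negFrac = 0) {
    idx <- which(runif(length(genes) * length(live)) < p)
    if (!length(idx)) return(NULL)
    gi <- ((idx - 1L) %% length(genes)) + 1L
    ti <- ((idx - 1L) %/% length(genes)) + 1L
    data.frame(gene = genes[gi], term = live[ti],
               negated = runif(length(idx)) < negFrac,
               stringsAsFactors = FALSE)
  }
  mk <- function(pairs, evidence, label) {
    if (is.null(pairs))
      pairs <- data.frame(gene = character(), term = character(),
                          negated = logical())
    annotationCorpus(gene = pairs$gene, term = pairs$term,
                     negated = pairs$negated, evidence = evidence,
                     reference = if (evidence == "IEA") "GO_REF:0000002"
                                 else "PMID:1",
                     releaseLabel = label)
  }
  oldElec <- rpairs(0.06)
  # new electronic: random subset of old records survive, plus new ones
  surv <- if (is.null(oldElec)) NULL
          else oldElec[runif(nrow(oldElec)) < 0.6, , drop = FALSE]
  newElec <- rbind(surv, rpairs(0.03))
  oldExp <- rpairs(0.02, negFrac = 0.15)
  survExp <- if (is.null(oldExp)) NULL
             else oldExp[runif(nrow(oldExp)) < 0.7, , drop = FALSE]
  newExp <- rbind(survExp, rpairs(0.04, negFrac = 0.2))

  old <- dropContradictoryPairs(bindCorpora(
    mk(oldElec, "IEA", "old"), mk(oldExp, "IDA", "old"),
    releaseLabel = "old"))$corpus
  newc <- dropContradictoryPairs(bindCorpora(
    mk(newElec, "IEA", "new"), mk(newExp, "IDA", "new"),
    releaseLabel = "new"))$corpus
  list(graph = g, old = old, new = newc)
}

nrow2 <- function(x) if (is.null(x)) 0L else nrow(x)

# Stratified closures for an instance, mirroring the pipeline's strata.
instanceClosures <- function(inst) {
  g <- inst$graph
  oldEval <- buildClosure(filterCorpus(inst$old, categories = "electronic"),
                          g, "electronic")
  newEval <- buildClosure(filterCorpus(inst$new, categories = "electronic"),
                          g, "electronic")
  oldRef <- buildClosure(filterCorpus(inst$old, categories = "experimental"),
                         g, "experimental")
  newRef <- buildClosure(filterCorpus(inst$new, categories = "experimental"),
                         g, "experimental")
  list(oldEval = oldEval, newEval = newEval, oldRef = oldRef,
       newRef = newRef, newRefNew = newReferenceClosure(newRef, oldRef))
}
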