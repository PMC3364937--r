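#' @import methods
#' @importFrom data.table data.table as.data.table setkey setkeyv := .N uniqueN rbindlist setDF setorder
#' @importFrom stats quantile wilcox.test rbinom runif
#' @importFrom utils head
NULL

# Relations over which annotations propagate to ancestors (GO true-path
# relations of the pre-regulates era).
.PROPAGATING_RELATIONS <- c("is_a", "part_of")

.GO_NAMESPACES <- c("biological_process", "molecular_function",
                    "cellular_component")

#' OntologyGraph: the Gene Ontology DAG
#'
#' Holds the terms of an ontology release, their names, namespaces and
#' obsolete flags, the typed child-to-parent edge list, and the alt_id
#' alias table. Reflexive ancestor sets over the propagating relations
#' (`is_a`, `part_of`, restricted to edges within a namespace) are
#' precomputed at construction, after validating acyclicity and root
#' reachability.
#'
#' @slot terms character vector of canonical term identifiers.
#' @slot termName named character, term id -> label.
#' @slot termNamespace named character, term id -> one of
#'   `biological_process`, `molecular_function`, `cellular_component`.
#' @slot obsolete named logical, term id -> obsolete flag.
#' @slot altIds named character, alias id -> canonical id.
#' @slot edges data.frame with columns `child`, `parent`, `relation`.
#' @slot ancestorSets named list, non-obsolete term id -> character vector
#'   of ancestors over propagating relations, including the term itself.
#' @slot roots named character? namespace -> root term id(s); stored as a
#'   character vector named by term id with namespace values.
#' @exportClass OntologyGraph
setClass("OntologyGraph",
         representation(terms = "character",
                        termName = "character",
                        termNamespace = "character",
                        obsolete = "logical",
                        altIds = "character",
                        edges = "data.frame",
                        ancestorSets = "list",
                        descendantSets = "list",
                        roots = "character"))

setValidity("OntologyGraph", function(object) {
  msg <- character()
  ns <- object@termNamespace
  bad <- setdiff(unique(ns), .GO_NAMESPACES)
  if (length(bad))
    msg <- c(msg, paste0("unknown namespace(s): ", paste(bad, collapse = ", ")))
  if (!all(object@terms %in% names(ns)))
    msg <- c(msg, "every term must have a namespace")
  if (anyDuplicated(object@terms))
    msg <- c(msg, "duplicated term identifiers")
  if (length(object@altIds) &&
      !all(object@altIds %in% object@terms))
    msg <- c(msg, "alt_id aliases must resolve to known terms")
  if (length(msg)) msg else TRUE
})

#' AnnotationCorpus: one GAF release
#'
#' A set of direct annotation records from a single release of an
#' annotation file, plus the release label (the file's release date is the
#' authoritative date; per-record date columns are carried but never used
#' for dating).
#'
#' @slot records data.frame with one row per annotation record; columns
#'   `db`, `gene`, `symbol`, `qualifier`, `negated`, `term`, `reference`,
#'   `evidence`, `withFrom`, `aspect`, `objectType`, `taxon`, `date`,
#'   `assignedBy`, `source`.
#' @slot releaseLabel single character, label of the release.
#' @exportClass AnnotationCorpus
setClass("AnnotationCorpus",
         representation(records = "data.frame",
                        releaseLabel = "character"))

.CORPUS_COLUMNS <- c("db", "gene", "symbol", "qualifier", "negated", "term",
                     "reference", "evidence", "withFrom", "aspect",
                     "objectType", "taxon", "date", "assignedBy", "source")

setValidity("AnnotationCorpus", function(object) {
  msg <- character()
  missing_cols <- setdiff(.CORPUS_COLUMNS, names(object@records))
  if (length(missing_cols))
    msg <- c(msg, paste0("records lack column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (length(object@releaseLabel) != 1L)
    msg <- c(msg, "releaseLabel must be a single string")
  if (!length(msg) && nrow(object@records) &&
      !is.logical(object@records$negated))
    msg <- c(msg, "negated must be logical")
  if (length(msg)) msg else TRUE
})

#' AnnotationClosure: ancestor-propagated annotation sets
#'
#' The inheritance closure of a corpus stratum over an ontology: for each
#' gene the set of positive (gene, term) pairs closed under ancestors, and
#' the set of directly asserted NOT terms (never propagated).
#'
#' @slot positive data.frame with columns `gene`, `term`: the
#'   ancestor-closed positive pairs (unique).
#' @slot negated data.frame with columns `gene`, `term`: directly asserted
#'   NOT pairs (unique, unpropagated).
#' @slot stratum character description of the selector the closure was
#'   built from.
#' @slot graphTerms character, sorted canonical term ids of the ontology
#'   the closure was built on (used to refuse mixing ontologies).
#' @exportClass AnnotationClosure
setClass("AnnotationClosure",
         representation(positive = "data.frame",
                        negated = "data.frame",
                        stratum = "character",
                        graphTerms = "character"))

setValidity("AnnotationClosure", function(object) {
  msg <- character()
  for (nm in c("positive", "negated")) {
    df <- slot(object, nm)
    if (!all(c("gene", "term") %in% names(df)))
      msg <- c(msg, paste0(nm, " must have columns gene, term"))
  }
  if (length(msg)) msg else TRUE
})

#' EvaluationConfig: thresholds and strata for a release-pair evaluation
#'
#' @slot minOldAnnotations minimum closure pairs a term needs in the old
#'   evaluated stratum to be reportable (default 10).
#' @slot minNewExperimental minimum closure pairs a term needs in the new
#'   reference stratum to be reportable (default 10).
#' @slot evaluatedCategory evidence category of the evaluated (older)
#'   stratum, default `electronic`.
#' @slot referenceCategory evidence category of the confirming/rejecting
#'   stratum, default `experimental`.
#' @slot sources optional electronic-source selector applied to the
#'   evaluated stratum.
#' @slot taxa optional taxon selector applied to all strata.
#' @slot namespaces optional namespace selector applied to all strata.
#' @exportClass EvaluationConfig
setClass("EvaluationConfig",
         representation(minOldAnnotations = "integer",
                        minNewExperimental = "integer",
                        evaluatedCategory = "character",
                        referenceCategory = "character",
                        sources = "character",
                        taxa = "integer",
                        namespaces = "character"))

setValidity("EvaluationConfig", function(object) {
  msg <- character()
  if (object@minOldAnnotations < 1L || object@minNewExperimental < 1L)
    msg <- c(msg, "thresholds must be >= 1")
  cats <- c("experimental", "curated", "electronic", "excluded")
  if (!object@evaluatedCategory %in% cats ||
      !object@referenceCategory %in% cats)
    msg <- c(msg, paste0("categories must be one of: ",
                         paste(cats, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: ground-truth parameters for the release-pair simulator
#'
#' @slot nTerms terms per namespace (including the root).
#' @slot maxParents maximum parents drawn per non-root term.
#' @slot nGenes number of genes carrying electronic annotations.
#' @slot annotationsPerGene mean electronic annotations per gene, in
#'   `[1, 3]`; each gene is annotated in that many distinct namespaces (at
#'   most one direct electronic annotation per namespace, which keeps the
#'   event-level ground truth identifiable at closure level).
#' @slot pConfirm,pReject,pRemove,pSpecialize,pUnchanged per-annotation
#'   event probabilities; must sum to 1.
#' @slot sourceMix named numeric over the six electronic source labels;
#'   must sum to 1.
#' @slot nBackground genes carrying old experimental annotations copied
#'   unchanged into the new release (disjoint pool).
#' @slot nNovel genes receiving new experimental annotations unrelated to
#'   any electronic annotation (coverage misses; disjoint pool).
#' @slot seed integer seed for the single pseudo-random stream.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nTerms = "integer",
                        maxParents = "integer",
                        nGenes = "integer",
                        annotationsPerGene = "numeric",
                        pConfirm = "numeric",
                        pReject = "numeric",
                        pRemove = "numeric",
                        pSpecialize = "numeric",
                        pUnchanged = "numeric",
                        sourceMix = "numeric",
                        nBackground = "integer",
                        nNovel = "integer",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  p <- c(object@pConfirm, object@pReject, object@pRemove,
         object@pSpecialize, object@pUnchanged)
  if (any(p < 0) || any(p > 1))
    msg <- c(msg, "event probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "event probabilities must sum to 1")
  if (object@nTerms < 1L || object@nGenes < 1L || object@maxParents < 1L)
    msg <- c(msg, "all sizes must be >= 1")
  if (object@annotationsPerGene < 1 || object@annotationsPerGene > 3)
    msg <- c(msg, "annotationsPerGene must lie in [1, 3]")
  if (!setequal(names(object@sourceMix), .ELECTRONIC_SOURCES))
    msg <- c(msg, paste0("sourceMix must be named by: ",
                         paste(.ELECTRONIC_SOURCES, collapse = ", ")))
  else if (abs(sum(object@sourceMix) - 1) > 1e-9 || any(object@sourceMix < 0))
    msg <- c(msg, "sourceMix must be a probability vector summing to 1")
  if (length(msg)) msg else TRUE
})

#' ReleaseEvaluation: the result of differencing two releases
#'
#' @slot termQuality data.frame, one row per evaluated GO term; see
#'   [termQuality()] for the column contract.
#' @slot config the [EvaluationConfig-class] used.
#' @slot log named list of pipeline bookkeeping counts (records read,
#'   contradictory pairs dropped, shared terms, stratum sizes).
#' @exportClass ReleaseEvaluation
setClass("ReleaseEvaluation",
         representation(termQuality = "data.frame",
                        config = "EvaluationConfig",
                        log = "list"))
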