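#' @rdname ancestors
#' @export
setGeneric("ancestors", function(graph, term) standardGeneric("ancestors"))

#' @rdname descendants
#' @export
setGeneric("descendants", function(graph, term) standardGeneric("descendants"))

#' @rdname sharedTerms
#' @export
setGeneric("sharedTerms",
           function(graphOld, graphNew) standardGeneric("sharedTerms"))

#' Accessors for OntologyGraph
#'
#' `termIds` returns the canonical term identifiers; `termNames` and
#' `termNamespaces` the label and namespace lookup vectors; `isObsolete`
#' the obsolete flags; `altIds` the alias table; `ontologyEdges` the typed
#' child-to-parent edge table; `namespaceRoots` the root term of each
#' namespace.
#'
#' @param x an [OntologyGraph-class].
#' @return see the individual descriptions.
#' @name ontology-accessors
#' @rdname ontology-accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname ontology-accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @rdname ontology-accessors
#' @export
setGeneric("termNamespaces", function(x) standardGeneric("termNamespaces"))

#' @rdname ontology-accessors
#' @export
setGeneric("isObsolete", function(x) standardGeneric("isObsolete"))

#' @rdname ontology-accessors
#' @export
setGeneric("altIds", function(x) standardGeneric("altIds"))

#' @rdname ontology-accessors
#' @export
setGeneric("ontologyEdges", function(x) standardGeneric("ontologyEdges"))

#' @rdname ontology-accessors
#' @export
setGeneric("namespaceRoots", function(x) standardGeneric("namespaceRoots"))

#' Accessors for AnnotationCorpus
#'
#' `records` returns the record table; `releaseLabel` the release's label.
#'
#' @param x an [AnnotationCorpus-class].
#' @name corpus-accessors
#' @rdname corpus-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname corpus-accessors
#' @export
setGeneric("releaseLabel", function(x) standardGeneric("releaseLabel"))

#' Accessors for AnnotationClosure
#'
#' `positivePairs` and `negatedPairs` return the (gene, term) pair tables;
#' `positiveTerms`/`negatedTerms` the term set of one gene.
#'
#' @param x an [AnnotationClosure-class].
#' @param gene a gene identifier.
#' @name closure-accessors
#' @rdname closure-accessors
#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))

#' @rdname closure-accessors
#' @export
setGeneric("negatedPairs", function(x) standardGeneric("negatedPairs"))

#' @rdname closure-accessors
#' @export
setGeneric("positiveTerms", function(x, gene) standardGeneric("positiveTerms"))

#' @rdname closure-accessors
#' @export
setGeneric("negatedTerms", function(x, gene) standardGeneric("negatedTerms"))

#' Accessors for ReleaseEvaluation
#'
#' `termQuality` returns the full per-term quality table; `reportable`
#' only the rows passing the configured annotation-count thresholds.
#'
#' @param x a [ReleaseEvaluation-class].
#' @name evaluation-accessors
#' @rdname evaluation-accessors
#' @export
setGeneric("termQuality", function(x) standardGeneric("termQuality"))

#' @rdname evaluation-accessors
#' @export
setGeneric("reportable", function(x) standardGeneric("reportable"))
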