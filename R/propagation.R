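# Inheritance closures, inheritance-aware term frequencies, and
# information-content specificity.

#' Build the inheritance closure of a corpus
#'
#' Applies the true-path rule: every positive annotation implies all
#' ancestors of its term, so each gene's positive set is the union of the
#' reflexive ancestor sets of its directly annotated terms. NOT
#' annotations are kept verbatim at their exact terms and are never
#' propagated (a NOT asserts absence of one specific function, not of
#' anything more general).
#'
#' @param corpus an [AnnotationCorpus-class] (hygiene-filtered; see
#'   [dropContradictoryPairs()]).
#' @param graph an [OntologyGraph-class]; all corpus terms must resolve in
#'   it, or an error lists the offending records.
#' @param stratum optional character tag describing the stratum the
#'   closure represents.
#' @return an [AnnotationClosure-class].
#' @export
buildClosure <- function(corpus, graph, stratum = "all") {
  rec <- corpus@records
  resolved <- resolveTermIds(graph, rec$term)
  bad <- is.na(resolved) | isObsolete(graph)[resolved]
  bad[is.na(bad)] <- TRUE
  if (any(bad))
    stop("record(s) with unresolvable or obsolete term(s): ",
         paste(head(unique(paste0(rec$gene[bad], " -> ", rec$term[bad])), 10L),
               collapse = "; "))
  pos_idx <- which(!rec$negated)
  anc <- graph@ancestorSets[resolved[pos_idx]]
  positive <- data.frame(gene = rep(rec$gene[pos_idx], lengths(anc)),
                         term = as.character(unlist(anc, use.names = FALSE)),
                         stringsAsFactors = FALSE)
  positive <- unique(positive)
  negated <- unique(data.frame(gene = rec$gene[rec$negated],
                               term = resolved[rec$negated],
                               stringsAsFactors = FALSE))
  rownames(positive) <- rownames(negated) <- NULL
  new("AnnotationClosure", positive = positive, negated = negated,
      stratum = stratum, graphTerms = sort(graph@terms))
}

## Closure accessors --------------------------------------------------------

#' @rdname closure-accessors
setMethod("positivePairs", "AnnotationClosure", function(x) x@positive)

#' @rdname closure-accessors
setMethod("negatedPairs", "AnnotationClosure", function(x) x@negated)

#' @rdname closure-accessors
setMethod("positiveTerms", "AnnotationClosure", function(x, gene) {
  x@positive$term[x@positive$gene == gene]
})

#' @rdname closure-accessors
setMethod("negatedTerms", "AnnotationClosure", function(x, gene) {
  x@negated$term[x@negated$gene == gene]
})

setMethod("show", "AnnotationClosure", function(object) {
  cat("AnnotationClosure [", object@stratum, "]: ",
      nrow(object@positive), " positive pairs over ",
      length(unique(object@positive$gene)), " genes; ",
      nrow(object@negated), " NOT pairs\n", sep = "")
})

#' Inheritance-aware term frequencies and information content
#'
#' Counts, for every term, the number of genes carrying the term in their
#' inheritance closure (gene-level presence: a gene contributes at most
#' one count per term, so duplicate records cannot distort the result).
#' Frequencies are normalized per namespace by the number of genes
#' annotated anywhere in that namespace — equivalently the namespace
#' root's count — so `freq(root) = 1`. Specificity is the information
#' content `ic = -log2(freq)` in bits; the root has ic 0 and every child
#' is at least as specific as each of its parents. Terms absent from the
#' closure are omitted (no infinite values).
#'
#' @param closure an [AnnotationClosure-class].
#' @param graph the [OntologyGraph-class] the closure was built on.
#' @return data.frame with columns `term`, `namespace`, `count`, `freq`,
#'   `ic`, sorted by term id.
#' @export
termFrequency <- function(closure, graph) {
  pos <- closure@positive
  if (!nrow(pos))
    stop("cannot compute term frequencies from an empty closure")
  ns_of <- termNamespaces(graph)
  dt <- data.table(gene = pos$gene, term = pos$term)
  dt[, namespace := ns_of[term]]
  counts <- dt[, .(count = .N), by = .(term, namespace)]
  denom <- dt[, .(total = uniqueN(gene)), by = namespace]
  counts <- merge(counts, denom, by = "namespace")
  counts[, freq := count / total]
  counts[, ic := -log2(freq)]
  out <- as.data.frame(counts[, .(term, namespace, count, freq, ic)])
  out <- out[order(out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Information content from a frequency table
#'
#' Returns the specificity `-log2(freq)` of every term in a frequency
#' table (see [termFrequency()]).
#'
#' @param table data.frame with columns `term` and `freq`.
#' @return named numeric vector, term -> ic in bits.
#' @export
informationContent <- function(table) {
  stopifnot(all(c("term", "freq") %in% names(table)))
  ok <- table$freq > 0
  ic <- -log2(table$freq[ok])
  names(ic) <- table$term[ok]
  ic
}

#' Write a term-frequency/IC table as TSV
#'
#' @param table data.frame from [termFrequency()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeICTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
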