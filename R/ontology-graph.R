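# Construction and DAG queries for OntologyGraph.

#' Build an OntologyGraph from components
#'
#' Low-level constructor used by the OBO parsers and the simulator.
#' Validates edge references, checks acyclicity of the propagating
#' relations (`is_a`, `part_of` within a namespace) and precomputes the
#' reflexive ancestor closure of every non-obsolete term.
#'
#' @param terms character vector of canonical term ids.
#' @param name named character, term -> label.
#' @param namespace named character, term -> namespace.
#' @param obsolete named logical, term -> obsolete flag.
#' @param altIds named character, alias -> canonical id.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @return an [OntologyGraph-class].
#' @export
makeOntologyGraph <- function(terms, name, namespace, obsolete,
                              altIds = character(), edges) {
  terms <- as.character(terms)
  if (!all(terms %in% names(name)) || !all(terms %in% names(namespace)) ||
      !all(terms %in% names(obsolete)))
    stop("name, namespace and obsolete must be named for every term")
  name <- name[terms]; namespace <- namespace[terms]
  obsolete <- obsolete[terms]
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges))
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)

  # resolve parent references through the alias table before validating
  if (length(altIds) && nrow(edges)) {
    hit <- edges$parent %in% names(altIds)
    edges$parent[hit] <- unname(altIds[edges$parent[hit]])
  }
  dangling <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(dangling))
    stop("edge(s) reference undefined term(s): ",
         paste(sort(dangling), collapse = ", "))

  live <- terms[!obsolete[terms]]
  prop <- edges[edges$relation %in% .PROPAGATING_RELATIONS &
                  !obsolete[edges$child] & !obsolete[edges$parent] &
                  namespace[edges$child] == namespace[edges$parent], ,
                drop = FALSE]

  anc <- .ancestorClosure(live, prop)

  has_parent <- unique(prop$child)
  roots <- setdiff(live, has_parent)
  root_ns <- namespace[roots]
  names(root_ns) <- roots

  # every non-obsolete, non-root term must reach a root of its namespace
  if (length(live)) {
    ok <- vapply(live, function(t) any(anc[[t]] %in% roots), logical(1))
    if (!all(ok))
      stop("term(s) cannot reach a namespace root over is_a/part_of: ",
           paste(head(live[!ok], 10L), collapse = ", "))
  }

  child <- rep(names(anc), lengths(anc))
  desc <- split(child, unlist(anc, use.names = FALSE))

  new("OntologyGraph", terms = terms, termName = name,
      termNamespace = namespace, obsolete = obsolete, altIds = altIds,
      edges = edges, ancestorSets = anc, descendantSets = desc,
      roots = root_ns)
}

# Kahn topological order + closure; errors naming a cycle if one exists.
.ancestorClosure <- function(live, prop) {
  anc <- vector("list", length(live))
  names(anc) <- live
  if (!length(live)) return(anc)

  parents_of <- split(prop$parent, factor(prop$child, levels = live))
  children_of <- split(prop$child, factor(prop$parent, levels = live))
  indeg <- lengths(parents_of)

  order <- character(length(live))
  queue <- live[indeg == 0L]
  done <- 0L
  indeg_mut <- indeg
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    done <- done + 1L
    order[[done]] <- t
    for (ch in children_of[[t]]) {
      indeg_mut[[ch]] <- indeg_mut[[ch]] - 1L
      if (indeg_mut[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done < length(live)) {
    cyc <- live[indeg_mut > 0L]
    stop("cycle detected over propagating relations involving: ",
         paste(sort(cyc), collapse = ", "))
  }
  for (t in order)
    anc[[t]] <- unique(c(t, unlist(anc[parents_of[[t]]],
                                   use.names = FALSE)))
  anc
}

#' Resolve term identifiers to canonical ids
#'
#' Maps each id through the graph's alt_id alias table; canonical ids map
#' to themselves, unknown ids to `NA`.
#'
#' @param graph an [OntologyGraph-class].
#' @param ids character vector of term ids.
#' @return character vector of canonical ids (`NA` where unknown).
#' @export
resolveTermIds <- function(graph, ids) {
  out <- ifelse(ids %in% graph@terms, ids, NA_character_)
  if (length(graph@altIds)) {
    miss <- is.na(out) & ids %in% names(graph@altIds)
    out[miss] <- unname(graph@altIds[ids[miss]])
  }
  out
}

#' Ancestors of a term
#'
#' The reflexive-transitive closure of a term over the propagating
#' relations (`is_a`, `part_of` within the term's namespace): the set of
#' terms the annotation implies under the true-path rule. Always contains
#' the term itself and its namespace root.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a term id (alt_id aliases are resolved).
#' @return character vector of ancestor term ids.
#' @export
setMethod("ancestors", "OntologyGraph", function(graph, term) {
  t <- .resolveOne(graph, term)
  graph@ancestorSets[[t]]
})

#' Descendants of a term
#'
#' The inverse of [ancestors()]: all terms whose ancestor set contains the
#' query. Reflexive.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a term id (alt_id aliases are resolved).
#' @return character vector of descendant term ids.
#' @export
setMethod("descendants", "OntologyGraph", function(graph, term) {
  t <- .resolveOne(graph, term)
  desc <- graph@descendantSets[[t]]
  if (is.null(desc)) t else desc
})

.resolveOne <- function(graph, term) {
  stopifnot(length(term) == 1L)
  t <- resolveTermIds(graph, term)
  if (is.na(t))
    stop("unknown term: ", term)
  if (graph@obsolete[[t]])
    stop("term is obsolete: ", t)
  t
}

#' Terms shared between two ontology releases
#'
#' Non-obsolete terms present (canonically, after alt_id resolution in
#' either direction) in both releases. The result is expressed in the
#' newer graph's canonical identifier space: a term merged into another in
#' the newer release contributes its merge target. Downstream per-term
#' outputs are restricted to this set.
#'
#' @param graphOld,graphNew two [OntologyGraph-class] objects.
#' @return sorted character vector of term ids (canonical in `graphNew`).
#' @export
setMethod("sharedTerms", signature("OntologyGraph", "OntologyGraph"),
          function(graphOld, graphNew) {
  liveOld <- graphOld@terms[!graphOld@obsolete[graphOld@terms]]
  liveNew <- graphNew@terms[!graphNew@obsolete[graphNew@terms]]

  fwd <- resolveTermIds(graphNew, liveOld)
  fwd <- fwd[!is.na(fwd) & fwd %in% liveNew]

  back <- resolveTermIds(graphOld, liveNew)
  bwd <- liveNew[!is.na(back) & back %in% liveOld]

  sort(unique(c(fwd, bwd)))
})

## Accessors ----------------------------------------------------------------

#' @rdname ontology-accessors
setMethod("termIds", "OntologyGraph", function(x) x@terms)

#' @rdname ontology-accessors
setMethod("termNames", "OntologyGraph", function(x) x@termName)

#' @rdname ontology-accessors
setMethod("termNamespaces", "OntologyGraph", function(x) x@termNamespace)

#' @rdname ontology-accessors
setMethod("isObsolete", "OntologyGraph", function(x) x@obsolete)

#' @rdname ontology-accessors
setMethod("altIds", "OntologyGraph", function(x) x@altIds)

#' @rdname ontology-accessors
setMethod("ontologyEdges", "OntologyGraph", function(x) x@edges)

#' @rdname ontology-accessors
setMethod("namespaceRoots", "OntologyGraph", function(x) x@roots)

setMethod("show", "OntologyGraph", function(object) {
  live <- sum(!object@obsolete)
  cat("OntologyGraph with", length(object@terms), "terms (",
      live, "non-obsolete ),", nrow(object@edges), "edges\n")
  ns <- table(object@termNamespace[!object@obsolete[object@terms]])
  for (n in names(ns)) cat("  ", n, ":", ns[[n]], "terms\n")
  if (length(object@altIds))
    cat("  ", length(object@altIds), "alt_id aliases\n")
})
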