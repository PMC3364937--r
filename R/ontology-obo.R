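# OBO 1.2 flat-file and OBO-XML readers, and an OBO 1.2 writer.

#' Parse an ontology file
#'
#' Reads a Gene Ontology release in OBO 1.2 flat-file format (the primary,
#' archival dialect) or OBO-XML. Obsolete terms are kept and flagged,
#' never dropped; `alt_id` aliases are recorded so merged identifiers stay
#' resolvable. `is_a` and `relationship:` lines become typed
#' child-to-parent edges; only `is_a` and `part_of` propagate annotations.
#'
#' @param path path to the ontology file.
#' @param dialect `"obo-flat"` (default) or `"obo-xml"`.
#' @return an [OntologyGraph-class].
#' @examples
#' obo <- system.file("extdata", "mini.obo", package = "GOAnnoQC")
#' g <- parseOntology(obo)
#' ancestors(g, "GO:0000003")
#' @export
parseOntology <- function(path, dialect = c("obo-flat", "obo-xml")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         "obo-flat" = .parseOboFlat(readLines(path, warn = FALSE)),
         "obo-xml" = .parseOboXml(path))
}

#' Parse OBO 1.2 text given as a character vector
#'
#' @param lines character vector, one element per line of an OBO file.
#' @return an [OntologyGraph-class].
#' @export
parseOntologyText <- function(lines) .parseOboFlat(lines)

.parseOboFlat <- function(lines) {
  stanza_start <- grep("^\\[", lines)
  if (!length(stanza_start))
    stop("no stanzas found: not an OBO flat file")
  is_term <- lines[stanza_start] == "[Term]"
  bounds <- c(stanza_start, length(lines) + 1L)

  terms <- character(); nm <- character(); ns <- character()
  obs <- logical(); alt_alias <- character(); alt_canon <- character()
  e_child <- character(); e_parent <- character(); e_rel <- character()

  for (i in seq_along(stanza_start)) {
    if (!is_term[[i]]) next
    from <- stanza_start[[i]] + 1L
    to <- bounds[[i + 1L]] - 1L
    body <- lines[seq.int(from, length.out = max(0L, to - from + 1L))]
    body <- body[nzchar(body)]
    tag <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:", "", body))
    val <- trimws(sub("!.*$", "", val))   # strip trailing comments

    id <- val[tag == "id"]
    if (length(id) != 1L)
      stop("malformed [Term] stanza starting at line ", stanza_start[[i]],
           ": expected exactly one id, got ", length(id))
    if (!grepl("^GO:\\d{7}$", id))
      stop("malformed term id '", id, "' at line ", stanza_start[[i]])

    terms <- c(terms, id)
    nm[id] <- if (any(tag == "name")) val[tag == "name"][1L] else id
    ns[id] <- if (any(tag == "namespace")) val[tag == "namespace"][1L]
              else NA_character_
    obs[id] <- any(tag == "is_obsolete" & val == "true")

    for (a in val[tag == "alt_id"]) {
      alt_alias <- c(alt_alias, a)
      alt_canon <- c(alt_canon, id)
    }
    for (p in val[tag == "is_a"]) {
      e_child <- c(e_child, id); e_parent <- c(e_parent, p)
      e_rel <- c(e_rel, "is_a")
    }
    for (r in val[tag == "relationship"]) {
      parts <- strsplit(r, "\\s+")[[1L]]
      if (length(parts) < 2L)
        stop("malformed relationship line in stanza at line ",
             stanza_start[[i]], ": '", r, "'")
      e_child <- c(e_child, id); e_parent <- c(e_parent, parts[[2L]])
      e_rel <- c(e_rel, parts[[1L]])
    }
  }
  if (!length(terms)) stop("no [Term] stanzas found")
  if (anyNA(ns)) {
    # terms without an explicit namespace inherit the file default if any
    def <- grep("^default-namespace:", lines, value = TRUE)
    if (length(def))
      ns[is.na(ns)] <- trimws(sub("^default-namespace:", "", def[[1L]]))
    else
      stop("term(s) without namespace: ",
           paste(names(ns)[is.na(ns)], collapse = ", "))
  }
  alt <- alt_canon
  names(alt) <- alt_alias
  makeOntologyGraph(terms = terms, name = nm, namespace = ns,
                    obsolete = obs, altIds = alt,
                    edges = data.frame(child = e_child, parent = e_parent,
                                       relation = e_rel,
                                       stringsAsFactors = FALSE))
}

.parseOboXml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//term")
  if (!length(nodes)) stop("no <term> elements found: not an OBO-XML file")
  one <- function(node, xp) {
    v <- xml2::xml_find_first(node, xp)
    if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
  }
  many <- function(node, xp) xml2::xml_text(xml2::xml_find_all(node, xp))

  terms <- character(); nm <- character(); ns <- character()
  obs <- logical(); alt_alias <- character(); alt_canon <- character()
  e_child <- character(); e_parent <- character(); e_rel <- character()
  for (node in nodes) {
    id <- one(node, "./id")
    if (is.na(id)) stop("<term> element without <id>")
    terms <- c(terms, id)
    nm[id] <- one(node, "./name")
    ns[id] <- one(node, "./namespace")
    obs[id] <- identical(one(node, "./is_obsolete"), "1") ||
      identical(one(node, "./is_obsolete"), "true")
    for (a in many(node, "./alt_id")) {
      alt_alias <- c(alt_alias, a); alt_canon <- c(alt_canon, id)
    }
    for (p in many(node, "./is_a")) {
      e_child <- c(e_child, id); e_parent <- c(e_parent, p)
      e_rel <- c(e_rel, "is_a")
    }
    rels <- xml2::xml_find_all(node, "./relationship")
    for (r in rels) {
      e_child <- c(e_child, id)
      e_parent <- c(e_parent, one(r, "./to"))
      e_rel <- c(e_rel, one(r, "./type"))
    }
  }
  if (anyNA(nm)) nm[is.na(nm)] <- terms[is.na(nm)]
  if (anyNA(ns)) stop("term(s) without namespace in OBO-XML")
  alt <- alt_canon
  names(alt) <- alt_alias
  makeOntologyGraph(terms = terms, name = nm, namespace = ns,
                    obsolete = obs, altIds = alt,
                    edges = data.frame(child = e_child, parent = e_parent,
                                       relation = e_rel,
                                       stringsAsFactors = FALSE))
}

#' Write an OntologyGraph as OBO 1.2
#'
#' Emits a flat OBO file that [parseOntology()] round-trips: term ids,
#' names, namespaces, obsolete flags, alt_ids, `is_a` and `relationship:`
#' lines.
#'
#' @param graph an [OntologyGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               "ontology: synthetic-go"), con)
  ed <- graph@edges
  alt_by_canon <- if (length(graph@altIds))
    split(names(graph@altIds), unname(graph@altIds)) else list()
  for (t in graph@terms) {
    out <- c("", "[Term]",
             paste0("id: ", t),
             paste0("name: ", graph@termName[[t]]),
             paste0("namespace: ", graph@termNamespace[[t]]))
    for (a in alt_by_canon[[t]]) out <- c(out, paste0("alt_id: ", a))
    sel <- ed$child == t
    if (any(sel)) {
      isa <- ed$parent[sel & ed$relation == "is_a"]
      oth <- ed[sel & ed$relation != "is_a", , drop = FALSE]
      if (length(isa))
        out <- c(out, paste0("is_a: ", isa))
      if (nrow(oth))
        out <- c(out, paste0("relationship: ", oth$relation, " ", oth$parent))
    }
    if (graph@obsolete[[t]]) out <- c(out, "is_obsolete: true")
    writeLines(out, con)
  }
  invisible(path)
}
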