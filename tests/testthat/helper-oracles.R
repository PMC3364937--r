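# Independent brute-force oracles. These work from raw edge tables and
# record data.frames by exhaustive path enumeration, never through the
# package's closure machinery.

# All terms reachable from `term` by following propagating child->parent
# edges (within a namespace), including the term itself.
oracleAncestors <- function(graph, term) {
  ed <- ontologyEdges(graph)
  ns <- termNamespaces(graph)
  prop <- ed[ed$relation %in% c("is_a", "part_of") &
               ns[ed$child] == ns[ed$parent], , drop = FALSE]
  seen <- character()
  walk <- function(x) {
    if (x %in% seen) return(invisible())
    seen <<- c(seen, x)
    for (p in prop$parent[prop$child == x]) walk(p)
  }
  walk(term)
  sort(seen)
}

oraclePairKey <- function(gene, term) paste(gene, term, sep = "\r")

# Brute-force closure pair keys of a record data.frame (gene, term,
# negated): the positive pairs after propagating every non-negated record
# to all its ancestors.
oracleClosureKeys <- function(rec, graph) {
  rec <- rec[!rec$negated, , drop = FALSE]
  if (!nrow(rec)) return(character())
  keys <- character()
  for (i in seq_len(nrow(rec)))
    keys <- c(keys, oraclePairKey(rec$gene[[i]],
                                  oracleAncestors(graph, rec$term[[i]])))
  sort(unique(keys))
}

oracleNotKeys <- function(rec) {
  rec <- rec[rec$negated, , drop = FALSE]
  sort(unique(oraclePairKey(rec$gene, rec$term)))
}

# Literal application of the four-outcome rule to every old evaluated
# closure pair, given the raw stratified record tables.
oracleClassify <- function(oldEvalRec, newEvalRec, oldRefRec, newRefRec,
                           graph) {
  oldEvalP <- oracleClosureKeys(oldEvalRec, graph)
  newEvalP <- oracleClosureKeys(newEvalRec, graph)
  oldRefP <- oracleClosureKeys(oldRefRec, graph)
  newRefP <- setdiff(oracleClosureKeys(newRefRec, graph), oldRefP)
  newNot <- setdiff(oracleNotKeys(newRefRec), oracleNotKeys(oldRefRec))

  parts <- strsplit(oldEvalP, "\r", fixed = TRUE)
  cls <- vapply(seq_along(oldEvalP), function(i) {
    k <- oldEvalP[[i]]
    if (k %in% newNot) "rejected_explicit"
    else if (k %in% newRefP) "confirmed"
    else if (!(k %in% newEvalP)) "removed"
    else "uninformative"
  }, character(1))
  out <- data.frame(gene = vapply(parts, `[[`, "", 1L),
                    term = vapply(parts, `[[`, "", 2L),
                    classification = cls, stringsAsFactors = FALSE)
  out[order(out$gene, out$term), , drop = FALSE]
}

# Literal coverage rule: every new reference closure pair is predicted or
# missed according to the old evaluated closure.
oracleCoverage <- function(oldEvalRec, oldRefRec, newRefRec, graph) {
  oldEvalP <- oracleClosureKeys(oldEvalRec, graph)
  oldRefP <- oracleClosureKeys(oldRefRec, graph)
  newP <- setdiff(oracleClosureKeys(newRefRec, graph), oldRefP)
  parts <- strsplit(newP, "\r", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[[`, "", 1L),
                    term = vapply(parts, `[[`, "", 2L),
                    predicted = newP %in% oldEvalP,
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$term), , drop = FALSE]
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (untied samples), matching the convention of doubling the tail that
# contains the observed U and capping at 1.
oracleMannWhitneyP <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  allRanks <- seq_len(n + m)
  us <- apply(combos, 2L, function(ix) sum(allRanks[ix]) - n * (n + 1) / 2)
  pLe <- mean(us <= uObs)
  pGe <- mean(us >= uObs)
  min(1, 2 * (if (uObs > n * m / 2) pGe else pLe))
}

# Type-7 quartile by the direct order-statistic formula.
oracleQuantile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}
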