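# Evidence-code categories, electronic-source attribution, qualifier
# hygiene, and corpus stratification.

# The three broad evidence categories. Codes absent from all three lists
# (curation-status ND, obsolete NR, and the ISO/ISA/ISM/IGC/IBA/IBD/IKR/IRD
# family, plus anything unknown) are excluded from analysis.
.EVIDENCE_EXPERIMENTAL <- c("EXP", "IMP", "IGI", "IPI", "IEP", "IDA")
.EVIDENCE_CURATED <- c("ISS", "RCA", "IC", "NAS", "TAS")
.EVIDENCE_ELECTRONIC <- "IEA"

.ELECTRONIC_SOURCES <- c("ec2go", "uniprot_subcell", "uniprotkb_kw",
                         "ensembl_compara", "hamap2go", "interpro")

#' Classify evidence codes into broad categories
#'
#' Maps each GO evidence code to one of `experimental` (EXP, IMP, IGI,
#' IPI, IEP, IDA), `curated` (ISS, RCA, IC, NAS, TAS), `electronic` (IEA)
#' or `excluded` (ND, NR, ISO, ISA, ISM, IGC, IBA, IBD, IKR, IRD, and any
#' unknown code). Total and case-normalizing.
#'
#' @param code character vector of evidence codes.
#' @return character vector of categories, same length as `code`.
#' @examples
#' classifyEvidence(c("IDA", "TAS", "iea", "ND", "XYZ"))
#' @export
classifyEvidence <- function(code) {
  code <- toupper(code)
  out <- rep("excluded", length(code))
  out[code %in% .EVIDENCE_EXPERIMENTAL] <- "experimental"
  out[code %in% .EVIDENCE_CURATED] <- "curated"
  out[code %in% .EVIDENCE_ELECTRONIC] <- "electronic"
  out
}

#' The shipped reference -> electronic-source mapping
#'
#' Electronic (IEA) annotations carry a GO_REF database reference that
#' identifies the inference pipeline. The shipped table covers the six
#' UniProt-GOA pipelines: Enzyme Commission cross-references (`ec2go`),
#' UniProt Subcellular Location (`uniprot_subcell`), UniProtKB keywords
#' (`uniprotkb_kw`), Ensembl Compara orthology projection
#' (`ensembl_compara`), HAMAP family rules (`hamap2go`) and InterPro
#' domain matches (`interpro`). Users may supply their own two-column
#' table instead (see [readSourceMap()]).
#'
#' @return named character vector, GO_REF id -> source label.
#' @export
defaultSourceMap <- function() {
  map <- .sourceMapCache$map
  if (is.null(map)) {
    path <- system.file("extdata", "goref_sources.tsv", package = "GOAnnoQC")
    if (!nzchar(path))   # during in-source development
      path <- file.path("inst", "extdata", "goref_sources.tsv")
    map <- readSourceMap(path)
    .sourceMapCache$map <- map
  }
  map
}
.sourceMapCache <- new.env(parent = emptyenv())

#' Read a reference -> source mapping table
#'
#' @param path a two-column tab-separated file: reference id, source label.
#' @return named character vector, reference -> source label.
#' @export
readSourceMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("reference", "source"))
  out <- df$source
  names(out) <- df$reference
  out
}

.sourceFromReference <- function(reference, map = defaultSourceMap()) {
  out <- unname(map[reference])
  out[is.na(out)] <- "other"
  out
}

#' Attribute electronic annotations to their source pipeline
#'
#' Maps the DB:Reference of IEA records to a source label via the mapping
#' table; unmapped references become `"other"`. Errors if any record is
#' not electronic (source attribution is only meaningful for IEA).
#'
#' @param x an [AnnotationCorpus-class], or a data.frame of records with
#'   columns `evidence` and `reference`.
#' @param map reference -> source mapping, default [defaultSourceMap()].
#' @return character vector of source labels, one per record.
#' @export
attributeSource <- function(x, map = defaultSourceMap()) {
  rec <- if (is(x, "AnnotationCorpus")) x@records else x
  if (any(toupper(rec$evidence) != "IEA"))
    stop("attributeSource applies only to electronic (IEA) records")
  .sourceFromReference(rec$reference, map)
}

#' Drop contradictory NOT/positive annotation pairs
#'
#' A gene product mapped to the same GO term both with and without the
#' NOT qualifier (a context-dependence artifact of isoform-blind
#' annotation files) is uninterpretable; all records for such
#' (gene, term) pairs are removed and the pairs reported. Idempotent.
#'
#' @param corpus an [AnnotationCorpus-class].
#' @return list with elements `corpus` (the filtered
#'   [AnnotationCorpus-class]) and `dropped` (data.frame of the removed
#'   `gene`/`term` pairs).
#' @export
dropContradictoryPairs <- function(corpus) {
  rec <- corpus@records
  key <- paste(rec$gene, rec$term, sep = "\r")
  bad <- intersect(key[rec$negated], key[!rec$negated])
  keep <- !(key %in% bad)
  dropped <- unique(rec[!keep, c("gene", "term")])
  rownames(dropped) <- NULL
  list(corpus = .makeCorpus(rec[keep, , drop = FALSE], corpus@releaseLabel),
       dropped = dropped)
}

#' Filter a corpus by evidence category, source, taxon, namespace or term
#'
#' Records must match every selector that is set; unset selectors impose
#' no constraint. Output is always a sub-multiset of the input. Any
#' stratum of annotations can be evaluated downstream by filtering first
#' (e.g. one electronic source, one organism).
#'
#' @param corpus an [AnnotationCorpus-class].
#' @param categories evidence categories (see [classifyEvidence()]).
#' @param sources electronic-source labels (implies IEA records only).
#' @param taxa numeric taxon ids.
#' @param namespaces GO namespaces; requires `graph`.
#' @param terms GO term ids; resolved through `graph` when given, and
#'   unknown ids are an error.
#' @param graph an [OntologyGraph-class], needed for `namespaces` and for
#'   alias resolution of `terms`.
#' @return a filtered [AnnotationCorpus-class].
#' @export
filterCorpus <- function(corpus, categories = NULL, sources = NULL,
                         taxa = NULL, namespaces = NULL, terms = NULL,
                         graph = NULL) {
  rec <- corpus@records
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(categories))
    keep <- keep & classifyEvidence(rec$evidence) %in% categories
  if (!is.null(sources))
    keep <- keep & !is.na(rec$source) & rec$source %in% sources
  if (!is.null(taxa))
    keep <- keep & !is.na(rec$taxon) & rec$taxon %in% as.integer(taxa)
  if (!is.null(namespaces)) {
    if (is.null(graph))
      stop("namespace filtering requires an OntologyGraph")
    t <- resolveTermIds(graph, rec$term)
    keep <- keep & !is.na(t) & termNamespaces(graph)[t] %in% namespaces
  }
  if (!is.null(terms)) {
    if (!is.null(graph)) {
      resolved <- resolveTermIds(graph, terms)
      if (anyNA(resolved))
        stop("unknown term(s) in filter: ",
             paste(terms[is.na(resolved)], collapse = ", "))
      t <- resolveTermIds(graph, rec$term)
      keep <- keep & !is.na(t) & t %in% resolved
    } else {
      keep <- keep & rec$term %in% terms
    }
  }
  .makeCorpus(rec[keep, , drop = FALSE], corpus@releaseLabel)
}
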