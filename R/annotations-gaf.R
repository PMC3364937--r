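# GAF 1.0 / 2.0 reading and writing.

.GAF_NCOL <- c(gaf1 = 15L, gaf2 = 17L)

#' Read a GAF annotation release
#'
#' Parses a tab-separated Gene Association File (GAF 2.0, 17 columns, or
#' GAF 1.0, 15 columns). Comment lines start with `!`. The qualifier
#' column is scanned for `NOT` (including compound qualifiers such as
#' `NOT|colocalizes_with`); the DB:Reference (column 6) and Assigned_by
#' (column 15) are retained for electronic-source attribution, which is
#' applied to IEA records via the shipped GO_REF mapping (see
#' [defaultSourceMap()]).
#'
#' @param path path to the GAF file.
#' @param dialect `"gaf2"` (default) or `"gaf1"`.
#' @param releaseLabel label of the release; defaults to the file name.
#'   The release label, not the per-record date column, is the
#'   authoritative date of every annotation in the file.
#' @param sourceMap reference -> source mapping table, as from
#'   [defaultSourceMap()].
#' @param strict if `TRUE` (default) a line with the wrong column count is
#'   an error naming the line; if `FALSE`, such lines are skipped with a
#'   warning listing their line numbers.
#' @return an [AnnotationCorpus-class].
#' @export
readGAF <- function(path, dialect = c("gaf2", "gaf1"),
                    releaseLabel = basename(path),
                    sourceMap = defaultSourceMap(), strict = TRUE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  parseGAFText(lines, dialect = dialect, releaseLabel = releaseLabel,
               sourceMap = sourceMap, strict = strict)
}

#' Parse GAF text given as a character vector
#'
#' @param lines character vector of GAF lines (with `!` comments).
#' @inheritParams readGAF
#' @return an [AnnotationCorpus-class].
#' @export
parseGAFText <- function(lines, dialect = c("gaf2", "gaf1"),
                         releaseLabel = "unnamed-release",
                         sourceMap = defaultSourceMap(), strict = TRUE) {
  dialect <- match.arg(dialect)
  want <- .GAF_NCOL[[dialect]]
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]

  fields <- strsplit(lines, "\t", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; tolerate want-1 only if
  # the line ends with a tab
  n <- lengths(fields)
  short_ok <- n == want - 1L & endsWith(lines, "\t")
  fields[short_ok] <- lapply(fields[short_ok], function(f) c(f, ""))
  n[short_ok] <- want
  bad <- n != want
  if (any(bad)) {
    msg <- paste0("line(s) with wrong column count (expected ", want, "): ",
                  paste(lineno[bad], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    fields <- fields[!bad]
    lineno <- lineno[!bad]
  }
  if (!length(fields))
    return(.makeCorpus(.emptyRecords(), releaseLabel))

  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  qualifier <- m[, 4L]
  negated <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                    function(q) "NOT" %in% q, logical(1))
  taxon_raw <- sub("^taxon:", "", sub("\\|.*$", "", m[, 13L]))
  taxon <- suppressWarnings(as.integer(taxon_raw))
  if (anyNA(taxon) && any(nzchar(taxon_raw[is.na(taxon)])))
    warning("unparsable taxon on line(s): ",
            paste(lineno[is.na(taxon) & nzchar(taxon_raw)], collapse = ", "),
            " (records kept with taxon unset)")

  rec <- data.frame(db = m[, 1L], gene = m[, 2L], symbol = m[, 3L],
                    qualifier = qualifier, negated = negated,
                    term = m[, 5L], reference = m[, 6L],
                    evidence = toupper(m[, 7L]), withFrom = m[, 8L],
                    aspect = m[, 9L], objectType = m[, 12L],
                    taxon = taxon, date = m[, 14L], assignedBy = m[, 15L],
                    stringsAsFactors = FALSE)
  rec$source <- ifelse(rec$evidence == "IEA",
                       .sourceFromReference(rec$reference, sourceMap),
                       NA_character_)
  .makeCorpus(rec, releaseLabel)
}

.emptyRecords <- function() {
  data.frame(db = character(), gene = character(), symbol = character(),
             qualifier = character(), negated = logical(),
             term = character(), reference = character(),
             evidence = character(), withFrom = character(),
             aspect = character(), objectType = character(),
             taxon = integer(), date = character(),
             assignedBy = character(), source = character(),
             stringsAsFactors = FALSE)
}

.makeCorpus <- function(records, releaseLabel) {
  new("AnnotationCorpus", records = records[, .CORPUS_COLUMNS, drop = FALSE],
      releaseLabel = as.character(releaseLabel))
}

#' Construct an AnnotationCorpus from fields
#'
#' Convenience constructor for building corpora in code (tests, examples,
#' the simulator). All per-record fields recycle to the longest.
#'
#' @param gene,term required character vectors.
#' @param negated,evidence,reference,taxon,db,symbol,withFrom,aspect,objectType,date,assignedBy
#'   optional record fields with GAF-appropriate defaults.
#' @param releaseLabel label of the release.
#' @param sourceMap reference -> source mapping for IEA records.
#' @return an [AnnotationCorpus-class].
#' @export
annotationCorpus <- function(gene, term, negated = FALSE, evidence = "IEA",
                             reference = "GO_REF:0000002", taxon = 9606L,
                             db = "UniProtKB", symbol = gene,
                             withFrom = "", aspect = "", objectType = "protein",
                             date = "20200101", assignedBy = "GOAnnoQC",
                             releaseLabel = "unnamed-release",
                             sourceMap = defaultSourceMap()) {
  n <- max(length(gene), length(term))
  rec <- data.frame(db = rep_len(db, n), gene = rep_len(gene, n),
                    symbol = rep_len(symbol, n),
                    qualifier = ifelse(rep_len(negated, n), "NOT", ""),
                    negated = rep_len(as.logical(negated), n),
                    term = rep_len(term, n),
                    reference = rep_len(reference, n),
                    evidence = toupper(rep_len(evidence, n)),
                    withFrom = rep_len(withFrom, n),
                    aspect = rep_len(aspect, n),
                    objectType = rep_len(objectType, n),
                    taxon = rep_len(as.integer(taxon), n),
                    date = rep_len(date, n),
                    assignedBy = rep_len(assignedBy, n),
                    stringsAsFactors = FALSE)
  rec$source <- ifelse(rec$evidence == "IEA",
                       .sourceFromReference(rec$reference, sourceMap),
                       NA_character_)
  .makeCorpus(rec, releaseLabel)
}

#' Write an AnnotationCorpus as GAF
#'
#' Emits a tab-separated GAF file which [readGAF()] round-trips
#' record-for-record on all retained fields.
#'
#' @param corpus an [AnnotationCorpus-class].
#' @param path output file path.
#' @param dialect `"gaf2"` (default, 17 columns) or `"gaf1"` (15 columns).
#' @return `path`, invisibly.
#' @export
writeGAF <- function(corpus, path, dialect = c("gaf2", "gaf1")) {
  dialect <- match.arg(dialect)
  rec <- corpus@records
  required <- c("gene", "term", "evidence")
  for (f in required) {
    miss <- is.na(rec[[f]]) | !nzchar(rec[[f]])
    if (any(miss))
      stop("record(s) missing required field '", f, "': row(s) ",
           paste(head(which(miss), 5L), collapse = ", "))
  }
  header <- if (dialect == "gaf2") "!gaf-version: 2.0" else "!gaf-version: 1.0"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(rec)) {
    taxon <- ifelse(is.na(rec$taxon), "", paste0("taxon:", rec$taxon))
    cols <- cbind(rec$db, rec$gene, rec$symbol, rec$qualifier, rec$term,
                  rec$reference, rec$evidence, rec$withFrom, rec$aspect,
                  "", "", rec$objectType, taxon, rec$date, rec$assignedBy)
    if (dialect == "gaf2") cols <- cbind(cols, "", "")
    writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

## Accessors ----------------------------------------------------------------

#' @rdname corpus-accessors
setMethod("records", "AnnotationCorpus", function(x) x@records)

#' @rdname corpus-accessors
setMethod("releaseLabel", "AnnotationCorpus", function(x) x@releaseLabel)

setMethod("show", "AnnotationCorpus", function(object) {
  rec <- object@records
  cat("AnnotationCorpus '", object@releaseLabel, "': ",
      nrow(rec), " records, ", length(unique(rec$gene)), " genes, ",
      length(unique(rec$term)), " terms\n", sep = "")
  if (nrow(rec)) {
    tab <- table(classifyEvidence(rec$evidence))
    cat("  evidence categories:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    if (any(rec$negated)) cat("  NOT-qualified records:",
                              sum(rec$negated), "\n")
  }
})

setMethod("length", "AnnotationCorpus", function(x) nrow(x@records))
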