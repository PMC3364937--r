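gafLine <- function(gene, term, evidence = "IEA", qualifier = "",
                    reference = "GO_REF:0000002", taxon = "taxon:9606") {
  paste(c("UniProtKB", gene, gene, qualifier, term, reference, evidence,
          "", "P", "", "", "protein", taxon, "20200101", "Src", "", ""),
        collapse = "\t")
}

test_that("GAF parsing preserves fields and flags NOT qualifiers", {
  lines <- c("!gaf-version: 2.0",
             gafLine("P1", "GO:0000001", "IEA"),
             gafLine("P2", "GO:0000002", "IDA", reference = "PMID:1"),
             gafLine("P3", "GO:0000002", "IDA", qualifier = "NOT",
                     reference = "PMID:2"),
             gafLine("P4", "GO:0000003", "IEA",
                     qualifier = "NOT|colocalizes_with"))
  corpus <- parseGAFText(lines, releaseLabel = "r1")
  rec <- records(corpus)
  expect_equal(nrow(rec), 4L)
  expect_identical(rec$evidence, c("IEA", "IDA", "IDA", "IEA"))
  expect_identical(rec$negated, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(rec$reference[1:2], c("GO_REF:0000002", "PMID:1"))
  expect_true(all(rec$taxon == 9606L))
  expect_identical(releaseLabel(corpus), "r1")
})

test_that("malformed lines are reported with their line numbers", {
  good <- vapply(1:9, function(i) gafLine(paste0("P", i), "GO:0000001"),
                 character(1))
  lines <- c("! comment line", good[1:4], "UniProtKB\tbroken\tline",
             good[5:9])
  expect_error(parseGAFText(lines), "line.*6")
  suppressWarnings(
    corpus <- parseGAFText(lines, strict = FALSE)
  )
  expect_equal(nrow(records(corpus)), 9L)
  expect_warning(parseGAFText(lines, strict = FALSE), "6")
})

test_that("unparsable taxon keeps the record with taxon unset", {
  lines <- c(gafLine("P1", "GO:0000001", taxon = "taxon:oops"),
             gafLine("P2", "GO:0000001"))
  expect_warning(corpus <- parseGAFText(lines), "taxon")
  rec <- records(corpus)
  expect_equal(nrow(rec), 2L)
  expect_true(is.na(rec$taxon[[1L]]))
  expect_equal(rec$taxon[[2L]], 9606L)
})

test_that("GAF writing round-trips on retained fields, both dialects", {
  sim <- generateReleasePair(simulationConfig(nGenes = 40L, nTerms = 25L,
                                              seed = 5L))
  keep <- c("db", "gene", "qualifier", "negated", "term", "reference",
            "evidence", "taxon", "date", "assignedBy", "source")
  for (dialect in c("gaf2", "gaf1")) {
    path <- withr::local_tempfile(fileext = ".gaf")
    writeGAF(sim$new, path, dialect = dialect)
    back <- readGAF(path, dialect = dialect)
    expect_identical(records(back)[keep], records(sim$new)[keep])
  }
  # empty corpus writes a header-only file
  empty <- annotationCorpus(gene = character(), term = character())
  path <- withr::local_tempfile(fileext = ".gaf")
  writeGAF(empty, path)
  expect_identical(readLines(path), "!gaf-version: 2.0")
  expect_equal(nrow(records(readGAF(path))), 0L)
})

test_that("writing a record with a missing required field errors", {
  corpus <- annotationCorpus(gene = c("P1", ""), term = "GO:0000001")
  expect_error(writeGAF(corpus, withr::local_tempfile()), "gene")
})

test_that("evidence codes map to the three broad categories", {
  expect_identical(classifyEvidence("IDA"), "experimental")
  expect_identical(
    unique(classifyEvidence(c("EXP", "IMP", "IGI", "IPI", "IEP", "IDA"))),
    "experimental")
  expect_identical(
    unique(classifyEvidence(c("ISS", "RCA", "IC", "NAS", "TAS"))),
    "curated")
  expect_identical(classifyEvidence("IEA"), "electronic")
  expect_identical(
    unique(classifyEvidence(c("ND", "NR", "ISO", "ISA", "ISM", "IGC",
                              "IBA", "IBD", "IKR", "IRD"))),
    "excluded")
  # total and case-normalizing: unknown codes are excluded, never errors
  expect_identical(classifyEvidence(c("iea", "tas", "ZZZ")),
                   c("electronic", "curated", "excluded"))
})

test_that("electronic sources come from the reference mapping", {
  corpus <- annotationCorpus(
    gene = c("P1", "P2", "P3"), term = "GO:0000001",
    reference = c("GO_REF:0000002", "GO_REF:0000023", "GO_REF:9999999"))
  expect_identical(attributeSource(corpus),
                   c("interpro", "uniprot_subcell", "other"))
  expect_identical(records(corpus)$source,
                   c("interpro", "uniprot_subcell", "other"))
  nonIEA <- annotationCorpus(gene = "P1", term = "GO:0000001",
                             evidence = "IDA", reference = "PMID:1")
  expect_error(attributeSource(nonIEA), "IEA")
  # the shipped table covers all six pipelines
  expect_setequal(unname(defaultSourceMap()),
                  c("ec2go", "uniprot_subcell", "uniprotkb_kw",
                    "ensembl_compara", "hamap2go", "interpro"))
})

test_that("contradictory NOT/positive pairs are fully discarded", {
  corpus <- bindCorpora(
    annotationCorpus(gene = "g", term = "GO:0000001", negated = TRUE,
                     evidence = "IDA", reference = "PMID:1"),
    annotationCorpus(gene = "g", term = c("GO:0000001", "GO:0000002")))
  out <- dropContradictoryPairs(corpus)
  rec <- records(out$corpus)
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$term, "GO:0000002")
  expect_identical(out$dropped,
                   data.frame(gene = "g", term = "GO:0000001",
                              stringsAsFactors = FALSE))
  # no contradictions: identity
  clean <- annotationCorpus(gene = c("a", "b"), term = "GO:0000001")
  expect_identical(records(dropContradictoryPairs(clean)$corpus),
                   records(clean))
  # idempotent
  again <- dropContradictoryPairs(out$corpus)
  expect_identical(records(again$corpus), records(out$corpus))
  expect_equal(nrow(again$dropped), 0L)
})

test_that("hygiene filtering satisfies the corpus invariant on random corpora", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:40, 1L)
    corpus <- annotationCorpus(
      gene = sample(paste0("g", 1:6), n, replace = TRUE),
      term = sample(sprintf("GO:%07d", 1:5), n, replace = TRUE),
      negated = runif(n) < 0.3,
      evidence = sample(c("IEA", "IDA"), n, replace = TRUE))
    rec <- records(dropContradictoryPairs(corpus)$corpus)
    # brute-force pair scan: no (gene, term) both negated and positive
    key <- paste(rec$gene, rec$term)
    expect_length(intersect(key[rec$negated], key[!rec$negated]), 0L)
  }
})

test_that("corpus filtering composes like set intersection", {
  g <- parseOntology(system.file("extdata", "mini.obo",
                                 package = "GOAnnoQC"))
  corpus <- bindCorpora(
    annotationCorpus(gene = "P1", term = "GO:0000003", taxon = 9606L),
    annotationCorpus(gene = "P2", term = "GO:0000011", taxon = 10090L,
                     evidence = "IDA", reference = "PMID:1"),
    annotationCorpus(gene = "P3", term = "GO:0000022", taxon = 9606L,
                     reference = "GO_REF:0000004"))
  expect_identical(records(filterCorpus(corpus,
                                        categories = "electronic"))$gene,
                   c("P1", "P3"))
  expect_identical(records(filterCorpus(corpus, taxa = 9606))$gene,
                   c("P1", "P3"))
  expect_identical(records(filterCorpus(corpus, sources = "interpro"))$gene,
                   "P1")
  expect_identical(
    records(filterCorpus(corpus, namespaces = "cellular_component",
                         graph = g))$gene, "P3")
  expect_error(filterCorpus(corpus, terms = "GO:1234567", graph = g),
               "unknown term")

  # composing selectors equals one combined selector
  a <- filterCorpus(filterCorpus(corpus, categories = "electronic"),
                    taxa = 9606)
  b <- filterCorpus(corpus, categories = "electronic", taxa = 9606)
  expect_identical(records(a), records(b))
  # output is always a subset of the input
  expect_true(all(records(a)$gene %in% records(corpus)$gene))
})
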