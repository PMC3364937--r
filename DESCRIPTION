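Package: GOAnnoQC
Title: Release-Based Quality Assessment of Gene Ontology Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the quality of electronic (IEA) Gene Ontology
    annotations by differencing two releases of a GAF annotation corpus
    against the GO DAG. For every GO term it computes specificity
    (information content of the inheritance-aware annotation frequency),
    reliability (the fraction of electronic closure pairs later confirmed
    by new experimental annotations rather than explicitly rejected with a
    NOT qualifier or silently removed) and coverage (the fraction of new
    experimental annotations that an earlier electronic annotation had
    predicted). Includes OBO 1.2 and GAF 1.0/2.0 readers and writers,
    evidence-code and electronic-source stratification, distribution
    summaries with Mann-Whitney release comparisons, and a seeded
    synthetic ontology/release-pair simulator with exported ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
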