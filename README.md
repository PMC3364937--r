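# GOAnnoQC

Release-based quality assessment of Gene Ontology annotations.

Most Gene Ontology (GO) annotations are *electronic*: assigned by
computational pipelines (evidence code IEA) without individual curator
supervision, and widely distrusted for exactly that reason. GOAnnoQC
implements a way to put numbers on that distrust. It differences two
releases of an annotation corpus (GAF files) against the GO DAG and uses
the experimental annotations that curators added in the newer release as
a gold standard to score the electronic annotations of the older one.
The package is for annotation-database maintainers, function-prediction
groups, and anyone deciding whether to keep or drop IEA annotations in
an enrichment or prediction workflow.

## The three measures

All accounting is done on **closure pairs**: a (gene, term) membership in
the annotation set propagated over the DAG's `is_a`/`part_of` relations
(the true-path rule), so an annotation to a term also asserts all of its
ancestors.

Every electronic closure pair of the older release is classified against
the newer release as

* **confirmed** — a new experimental annotation to the term or any
  descendant implies it;
* **rejected** — a new experimental annotation with a `NOT` qualifier
  contradicts the exact term (`NOT` never propagates); or the pair has
  silently **removed** (implicit rejection);
* **uninformative** — unchanged; it enters no ratio.

For a term *i* with confirmed set *C<sub>i</sub>* and rejected-or-removed
set *R<sub>i</sub>*:

> reliability(i) = |C<sub>i</sub>| / (|C<sub>i</sub>| + |R<sub>i</sub>|)

Symmetrically, every *new* experimental closure pair is **predicted** if
the older release's electronic closure already contained it, else
**missed**; with predicted set *P<sub>i</sub>* and missed set
*M<sub>i</sub>*:

> coverage(i) = |P<sub>i</sub>| / (|P<sub>i</sub>| + |M<sub>i</sub>|)

The **specificity** of a term is its information content,
IC(i) = −log₂ freq(i), where freq is the inheritance-aware annotation
frequency normalized per namespace (the root of each ontology has
frequency 1 and IC 0, and a child is always at least as specific as its
parents).

Because closure membership does the bookkeeping, the DAG subtleties come
out right automatically: replacing an annotation by a descendant is not a
removal; an experimentally ascertained descendant confirms every implied
ancestor; a *less* specific new experimental annotation confirms only the
ancestral subset it implies and leaves the deeper pairs uninformative.

Evidence codes are grouped into **experimental** (EXP, IMP, IGI, IPI,
IEP, IDA), **curated** (ISS, RCA, IC, NAS, TAS) and **electronic** (IEA);
ND, NR, ISO, ISA, ISM, IGC, IBA, IBD, IKR, IRD and unknown codes are
excluded. Electronic annotations are attributed to their inference
pipeline (InterPro, UniProtKB keywords, UniProt Subcellular Location,
Enzyme Commission, HAMAP, Ensembl Compara) through the GAF reference
column, so any stratum — one source, one organism, one namespace, or the
curated category instead of the electronic one — can be evaluated with
the same machinery.

## Worked example

A miniature ontology and release pair ship with the package: three genes
annotated electronically in the old release; in the new release one gains
a confirming experimental annotation, one is contradicted by an
experimental `NOT` (and its IEA record dropped), and one disappears.

```r
library(GOAnnoQC)

obo <- system.file("extdata", "mini.obo",     package = "GOAnnoQC")
old <- readGAF(system.file("extdata", "mini_old.gaf", package = "GOAnnoQC"))
new <- readGAF(system.file("extdata", "mini_new.gaf", package = "GOAnnoQC"))
g   <- parseOntology(obo)

ev <- evaluateReleasePair(old, new, g, config = evaluationConfig(1, 1))
termQuality(ev)[, c("term", "name", "n_confirmed", "n_rejected_explicit",
                    "n_removed", "reliability", "coverage", "specificity")]
#>         term                       name n_confirmed n_rejected_explicit
#> 1 GO:0000001    biological process root           1                   0
#> 2 GO:0000002     organelle organization           1                   1
#> 3 GO:0000003 mitochondrion organization           1                   0
#>   n_removed reliability coverage specificity
#> 1         2   0.3333333        1   0.0000000
#> 2         1   0.3333333        1   0.0000000
#> 3         1   0.5000000        1   0.5849625
```

Reading the `GO:0000002` row: of its three electronic closure pairs, one
was confirmed by the new experimental annotation, one explicitly rejected
by the `NOT`, one removed with the vanished gene — reliability 1/3. Its
single new experimental closure pair was already predicted electronically
— coverage 1. (With realistic corpora you would keep the default
`evaluationConfig()` thresholds, which report only terms having at least
10 electronic closure pairs in the old release and 10 experimental ones
in the new.)

A command-line front end with the same functionality is installed at
`exec/goaq` (`goaq evaluate`, `goaq ic`, `goaq simulate`,
`goaq compare`).

## Simulated release pairs

Because historical database releases are large and mutable, the package
contains a seeded simulator that generates an ontology and an old/new
release pair in which every electronic annotation undergoes a known
event (confirm / reject / remove / specialize / unchanged) at configured
rates, and exports the resulting ground-truth tallies:

```r
sim <- generateReleasePair(simulationConfig(nGenes = 1000, seed = 1))
sim$truth$expectedReliability   # pConfirm / (pConfirm + pReject + pRemove)
```

The test suite uses it to check the whole pipeline against exact
ground-truth pair counts and against brute-force oracles.

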