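---
title: "Measuring the quality of electronic GO annotations from release differences"
author: "GOAnnoQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the quality of electronic GO annotations from release differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOAnnoQC)
```

## The idea

Electronic Gene Ontology annotations — those assigned by computational
pipelines under evidence code IEA — vastly outnumber curated ones, yet
their correctness is rarely measured. GOAnnoQC treats successive releases
of an annotation corpus as a natural experiment: experimental annotations
that curators add *between* two releases are an (expensive, trusted) gold
standard against which the older release's electronic annotations can be
scored, term by term.

Three per-term measures result:

* **reliability** — of the electronic assertions that received a verdict
  during the interval, the fraction confirmed rather than rejected or
  removed;
* **coverage** — of the experimental annotations newly added, the
  fraction an electronic annotation had already predicted;
* **specificity** — the information content of the term, measuring how
  much an annotation to it actually says.

## The model and its accounting unit

Everything is counted on **closure pairs**. The GO is a DAG; annotation
to a term implies annotation to all its ancestors over the propagating
relations (the true-path rule). A gene's closure is the union of the
reflexive ancestor sets of its directly annotated terms. We propagate
over `is_a` and `part_of` only: these are the classical true-path
relations, other relationship types (e.g. regulatory ones) are parsed and
retained but do not propagate, and `part_of` edges that cross namespaces
do not propagate either, so the three ontologies stay separate
throughout.

Each electronic closure pair (g, t) of the older release receives exactly
one label against the newer release:

1. **rejected** if the new experimental stratum asserts NOT on exactly
   (g, t). A NOT qualifier is a curator's exact-term assertion of
   absence; it never propagates in either direction.
2. otherwise **confirmed** if t is in g's *new* experimental closure — a
   new experimental annotation at t or any descendant implies t. Because
   the test is closure membership, a less specific new experimental
   annotation confirms exactly the ancestral subset it implies and
   leaves deeper electronic pairs unlabeled.
3. otherwise **removed** if t has left g's electronic closure in the new
   release. Again because the test is on the closure, an annotation
   replaced by a more specific descendant is *not* counted as removed —
   the descendant still implies it.
4. otherwise **uninformative**; such pairs enter no ratio, and a term
   whose pairs are all uninformative has *undefined* reliability
   (reported as missing, never coerced to 0 or 1).

"New" experimental annotations are those absent from the older release's
experimental closure; an assertion already experimentally implied before
the interval can neither confirm anything nor count as a coverage event.
Coverage classifies each new experimental closure pair as predicted
(already present in the old electronic closure) or missed.

Two deliberate tie-breaks are worth stating. First, when a gene
simultaneously gains an exact-term NOT and a confirming experimental
descendant elsewhere, the explicit curator contradiction wins
(rejected > confirmed > removed > uninformative is the precedence
order). Second, a (gene, term) pair annotated both with and without NOT
in the same release — an artifact of isoform-blind annotation files — is
uninterpretable, and all records for that pair are discarded before any
closure is built.

Counting closure pairs rather than annotation lines also makes the
measures robust to duplicate records: a gene contributes at most one
count per term per stratum.

## Specificity

The frequency of a term is the number of genes carrying it in their
closure, divided by the number of genes annotated anywhere in that
term's namespace — equivalently the namespace root's count, so
freq(root) = 1. Specificity is the information content

$$\mathrm{IC}(i) = -\log_2 \mathrm{freq}(i)$$

in bits. The logarithm base only rescales the axis; base 2 is this
package's convention. Under inheritance-aware counting, IC is zero at
each root and non-decreasing along every child-to-parent edge, which the
test suite checks on randomized corpora. Terms absent from a closure are
omitted from the table rather than given infinite IC. One caveat of the
normalization: annotating a previously *unannotated* gene enlarges the
namespace denominator and can raise other terms' IC, so the monotonicity
property "adding annotations never increases IC" is guaranteed — and
tested — for annotations added to genes already counted in the
namespace.

## Strata, thresholds and comparisons

Evidence codes are grouped into experimental (EXP, IMP, IGI, IPI, IEP,
IDA), curated (ISS, RCA, IC, NAS, TAS) and electronic (IEA); codes that
track curation status (ND), are obsolete (NR) or are too rare to
calibrate (ISO, ISA, ISM, IGC, IBA, IBD, IKR, IRD) are excluded, as is
any unknown code (never an error, so future codes cannot break parsing).
Electronic annotations are attributed to their generating pipeline via
the GAF reference column through a user-overridable mapping table whose
shipped default covers the six classical sources (InterPro, UniProtKB
keywords, UniProt Subcellular Location, Enzyme Commission, HAMAP,
Ensembl Compara); unmapped references become `other`.

`evaluateReleasePair()` evaluates the electronic stratum against the
experimental one by default, but the evaluated category, source, taxon
and namespace are all selectors: evaluating curated annotations, one
pipeline, or one organism is the same code path. Ontology structure may
itself drift between releases, so per-term output is restricted to terms
present (after `alt_id` merge resolution) and non-obsolete in both
ontology releases; propagation uses the newer release's graph.

Terms with fewer than 10 electronic closure pairs in the old release or
fewer than 10 experimental closure pairs in the new (defaults of
`evaluationConfig()`) are flagged not reportable: the full table keeps
them, `reportable()` drops them. Distributions of per-term measures are
summarized by quartiles (linear interpolation between order statistics,
`quantile` type 7 — box-plot conventions differ, so this is pinned
down), the mean, and outliers beyond 1.5 interquartile ranges from the
nearer quartile; two release intervals are compared with a two-sided
Mann-Whitney U test (with tie correction, exact for small untied
samples), flagged at the 0.05 level.

## The simulator: what it emulates and what it does not

Real historical releases are hundreds of megabytes and archive
availability drifts, so validation rests on a seeded simulator that
generates the *entire* study design with known ground truth:

* a rooted random DAG per namespace (each non-root term draws 1 to
  `maxParents` parents among earlier terms, guaranteeing acyclicity;
  roughly one edge in ten is `part_of`);
* an older release of electronic annotations (sources drawn from a
  configurable mix, defaulting to a domain/keyword-dominated blend) plus
  a background of experimental annotations carried unchanged;
* a newer release derived by drawing one event per electronic
  annotation: confirm (a new experimental annotation at the term or a
  random descendant), reject (a new experimental NOT at the exact term,
  with the contradicted IEA record dropped, as curation pipelines do),
  remove, specialize (replace by a random proper descendant; terms
  without descendants fall back to unchanged and are tallied as such),
  or unchanged;
* novel experimental annotations on a disjoint gene pool, providing
  coverage misses with ground truth independent of the reliability
  events.

Three design choices make the ground truth *exactly* recoverable rather
than approximate. Events are drawn per direct annotation while the
engine counts closure pairs, so the DAG semantics are genuinely
exercised rather than mirrored. Each gene carries at most one electronic
annotation per namespace, so no annotation's closure can mask another's
removal. And because a reject event also drops the contradicted
electronic annotation, every event type touches the full ancestor set of
its term, which makes the pooled closure-pair reliability identify
p_confirm / (p_confirm + p_reject + p_remove) independent of term depth.
The generator therefore emits, alongside the two GAF files and the OBO
ontology, the exact expected closure-pair tallies, which the test suite
requires the pipeline to reproduce to the pair.

Default rates (confirm 0.15, reject 0.05, remove 0.10, specialize 0.10,
unchanged 0.60) give an expected reliability of 0.5, of the order
observed for real electronic corpora; all sizes and rates are
configurable.

What the simulator does *not* emulate: curator attention bias toward
model organisms and popular proteins, literature-driven correlation
between a gene's annotations, ontology restructuring between releases
(terms are stable within a simulated pair), and realistic per-source
error profiles. Passing the simulation-based tests therefore
demonstrates that the engine measures what it defines — not that real
electronic annotations have any particular quality; on real data the
measures remain estimates conditioned on where curators chose to look.

## Numerical and degenerate-input conventions

* Undefined ratios (0/0) are `NA`, never 0 or 1.
* Frequency tables omit unannotated terms; no infinite IC values exist.
* Obsolete ontology terms are parsed and flagged, never silently
  dropped; queries on them are errors, and closures refuse unresolvable
  terms listing the offending records.
* Cycles over propagating relations and dangling parent references are
  construction-time errors naming the culprits.
* Records with unparsable taxa are kept with the taxon unset (warning);
  malformed GAF lines are an error naming the line, or skipped with a
  warning under `strict = FALSE`.
* All randomness flows from one integer seed per simulation; identical
  seeds give byte-identical emitted files.

## Validation problem sizes

The shipped test suite validates the classifier and coverage engine
against a brute-force oracle (literal rule application with ancestors by
exhaustive path enumeration) on 200 random release pairs of up to 15
terms per namespace and 30 genes; checks IC invariants on randomized
corpora; verifies exact ground-truth recovery on mid-sized simulations
(hundreds of genes) and statistical recovery of configured event rates
on a 10,000-gene simulation; and compares Mann-Whitney p-values against
exact rank-permutation enumeration for all sample sizes up to 8 per
group. `scripts/acceptance.R` reruns the 10,000-gene end-to-end
recovery from a user-supplied seed.

## Known limitations

* Isoform-level qualifiers (GAF column 17) are not resolved; the NOT
  hygiene rule is the blunt instrument standing in for them.
* Only subsumption closure is implemented — no relation composition or
  cross-ontology reasoning, and no semantic-similarity measures beyond
  per-term IC.
* Reliability conflates "wrong" with "withdrawn for other reasons":
  a removed annotation may have been dropped for pipeline bookkeeping
  rather than falsity; conversely an unconfirmed annotation may simply
  never have been looked at. The uninformative category absorbs the
  latter but nothing can separate the former.
* Release labels, not per-record dates, define the interval; corpora
  assembled from mixed-date fragments should be split by hand first.
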