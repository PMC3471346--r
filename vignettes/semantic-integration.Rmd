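---
title: "Semantic integration of methylation and expression data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic integration of methylation and expression data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semweave)
library(dplyr)
```

## The integration model

semweave answers questions of the form *"in which samples are the genes
that were methylated before demethylating treatment, and re-expressed
after it, enriched for a biological process or for a transcription
factor's targets?"* It does so by expressing three heterogeneous sources
in one RDF vocabulary and merging them on a shared gene identifier.

**Quantitative observations.** Each measurement (one value for one gene in
one sample in one dataset) becomes a *measurement datum* node carrying the
numeric value through *has measurement value* (IAO_0000004), dataset
membership through *part of*, and two *is about* links (IAO_0000136): one
to the sample — an OBI *cell culture* (OBI_0100060) — and one to the
reporter, an SO *transcript*. Samples, datasets and reporters carry Dublin
Core titles; reporters additionally carry their RefSeq accession as
`dc:identifier` and are named by Bio2RDF-style URIs
(`http://bio2rdf.org/refseq:NM_000546`). The RefSeq URI is the merge key:
every module emits byte-identical URIs for the same accession, and version
suffixes are stripped so transcripts join across sources.

**Gene Ontology annotations.** GO terms become SKOS `Concept` instances
and `is_a` edges become `skos:broader` links. Because the hierarchy is then
a relation between *individuals* rather than classes, annotation
propagation is a property-chain rule: if a gene *participates in* a
process and a second concept is *broader* than it, the gene participates
in the broader process too (and likewise for *has function* and *part
of*). `entail_go()` materialises this to fixpoint by forward chaining.
For these Horn rules forward chaining is semantically equivalent to
running a DL reasoner over the corresponding OWL 2 property-chain axioms,
and it is exactly reproducible. Propagation never crosses aspects.

**Transcription factor networks.** A factor *corresponds to* the genes
that express it and *regulates* its targets. Two chains are materialised
by `entail_tf()`: *coregulates* (expressing gene → each target of the
factor) and *indirectly coregulates* (pairs joined by a coregulates path
of length ≥ 2). Because regulated genes often express factors themselves,
the network is recursive and may contain cycles; the closure is computed
by iterated joins to fixpoint, which handles cycles naturally.

## Decisions where the design was open

* **Direction of `corresponds_to`.** The property is described
  factor-to-gene in one place and bound gene-to-factor in the stored
  query. Both directions are materialised so either phrasing holds; this
  costs one extra triple per expressing gene and removes the ambiguity.
* **Depth of indirect coregulation.** A strict reading of the single
  chain axiom yields only length-2 paths; the stated intent is the "full
  sphere of influence". The default is full reachability
  (`indirect_depth = "inf"`), with `"2"` available for the strict
  reading.
* **Self-edges.** Entailment over a cycle genuinely produces
  `g coregulates g`; `allow_self = TRUE` is therefore the default, with
  suppression available. Suppression is applied to the derived output
  after the closure is computed, so reachability through a cycle is not
  affected.
* **GO term IRIs.** Concept nodes use
  `http://purl.org/obo/owl/GO#0006915`-style IRIs (bare digits), because
  that is what the `go:` prefix in the stored queries resolves to; any
  other local form would make those queries unsatisfiable.
* **Negative and weak annotations.** `NOT`-qualified GAF records are
  dropped (treating a negative assertion as positive would be wrong); no
  evidence-code filtering is applied by default, with an exclusion list
  available, since the analyses here are rank- and count-based.
* **One-to-many symbol maps** expand to all RefSeq accessions: reporters
  are transcript-level, so dropping secondary accessions would silently
  lose joins.
* **Duplicate observations.** One value per (dataset, sample, reporter)
  is assumed by every analysis; duplicated rows keep the last value with
  a warning.
* **Strict vs report counting.** The stored pathway query has inner-join
  semantics: a sample with zero passing proliferation genes simply
  disappears from its results. Reported contrasts, however, are expected to
  list such samples with a zero count and a zero ratio. `mode = "report"`
  (default) lists every sample; `mode = "strict"` reproduces the query
  exactly and is what the engine/oracle equivalence tests use.
* **Fisher test orientation.** Enrichment of highly expressed genes among
  a factor's targets is scored one-sided (`greater`), the enrichment
  direction; a two-sided mode (minimum-likelihood convention: sum of all
  tables with point probability not exceeding the observed one) is also
  provided. The universe is the set of genes observed in the ratio
  dataset for that sample — the only universe actually available to the
  analysis.
* **"Regulated by the factor"** means direct targets plus the
  coregulates/indirectly-coregulates influence set of the genes
  expressing the factor (`relation = "influence"`), with
  `relation = "direct"` restricting to direct targets.

## Thresholds

All cutoffs are strict inequalities, matching the `FILTER (x > c)`
operators of the stored queries.

| parameter | default | meaning |
|---|---|---|
| `methylation_min` | 2 | relative methylation defining "methylated before treatment" |
| `expression_ratio_min` | 1 | post/pre expression ratio for the pathway contrast |
| `tf_expression_ratio_min` | 0.5 | ratio cutoff in the factor-candidate query |
| `high_expression_min` | 1 | ratio defining "highly expressed" in enrichment counts |

The two dataset titles (`"Methylation Relative"`,
`"AZA Pre-Post Treatment Ratios"`) are configuration, not constants, so
the same analyses run on differently named datasets.

## The SPARQL engine

The built-in engine covers the SPARQL 1.1 fragment the stored queries
use: basic graph patterns, `FILTER` comparison and arithmetic, `SELECT`
(plain and expression projections), `DISTINCT`, `COUNT` /
`COUNT(DISTINCT)`, `GROUP BY`, `ORDER BY`, and `DESCRIBE`. Evaluation
encodes every RDF term in its N-Triples form so joins and `DISTINCT` are
string operations; numeric comparison applies to literals whose datatype
is numeric (observation values are typed `xsd:double` and printed with 17
significant digits, so they round-trip exactly through serialization).
Filters on unbound or non-numeric operands evaluate to false, per
effective-boolean-value semantics. `ORDER BY` uses a byte-wise (radix)
sort so row order is locale-independent.

The two case-study queries ship verbatim under `inst/sparql/`, with two
typesetting defects repaired: a triple pattern that was printed as a
comment although its variable is used in a filter (restored as an active
pattern), and a `PREFIX` keyword missing its first letter. Each query has
an independent set-logic twin (`pathway_contrast_counts()`,
`tf_candidates()`); the test suite requires row-identical results from
both routes on synthetic models across many seeds.

## What the synthetic generator emulates — and what it does not

`simulate_study()` emulates the seven-cell-line design: 7 samples, 5
planted sensitive and 2 resistant; a rooted concept DAG whose apoptosis
and proliferation subtrees sit under real anchor accessions (GO:0006915,
GO:0008283 under GO:0008150); RefSeq-shaped accessions annotated into
those subtrees (1–3 aspect-P annotations each, default 30% apoptosis,
10% proliferation, remainder annotated to the root); a partially
recursive factor network (per-factor probability `cycle_prob` of
regulating another factor's expressing gene); and two observation
datasets in which an apoptosis gene passes both analysis filters with
probability 0.30 in sensitive samples and 0.05 in resistant ones, against
a 0.05 background.

Values are drawn from a two-component distribution — hits from
(2.5, 8) methylation and (1.5, 5) ratio, non-hits below both cutoffs —
rather than from any model of MeDIP array physics: the analyses consume
only threshold crossings, so hit indicators are the sufficient statistic.
Consequently, passing tests demonstrate the correctness of the semantic
machinery and the recoverability of a planted rate difference; they say
nothing about array noise, probe effects, dose–response (IC50) behaviour,
or the biological fidelity of real annotation densities. Generation is
fully deterministic given the configuration, and every ground-truth
oracle (ancestor sets, coregulation closures, per-sample hit sets) is
computed with plain set and matrix code, never by the entailment code it
later validates.

## Numerical and degenerate-input choices

* Numeric literals are serialized with `%.17g`, so
  `as.numeric(serialized) == original` exactly.
* `fisher_exact()` computes the greater tail with `phyper` and the
  two-sided value by summing hypergeometric point masses
  `<= p_obs * (1 + 1e-7)`; the relative tolerance guards ties against
  floating-point loss, the same convention `stats::fisher.test` uses. An
  all-zero-margin table returns 1; an empty table is an error.
* Ratios with a zero denominator are reported as 0 (a sample with no
  passing proliferation genes is a real, reportable outcome, not a
  missing value).
* An absent sample title in `describe_sample()` yields an empty graph;
  an absent dataset title in an analysis is an error naming the dataset;
  an unknown factor is an error.
* Cyclic `is_a` input is rejected at parse time with one cycle spelled
  out; obsolete terms are removed together with their edges before the
  check.

## Problem sizes used by the validation suite

The suite validates entailment on 100 random DAGs (up to 200 terms and
500 genes), the coregulation closure on 100 random digraphs (cycles and
self-loops included, all four depth/self-edge settings), query/set-logic
equivalence on 25 synthetic studies, Fisher p-values against full
enumeration for every 2×2 table with n ≤ 60, and planted-signal recovery
over 200 replicates at the study conditions (300 apoptosis genes in a
500-gene universe — 100 proliferation, 100 background — 7 samples, rates
0.30/0.05/0.05). These sizes give well-conditioned, exactly checkable
cases while keeping each property exhaustive where exhaustiveness is
feasible (Fisher) and randomised where it is not.

## Known limitations

* The SPARQL engine is a subset: no `OPTIONAL`, `UNION`, property paths,
  subqueries, or named graphs. Queries outside the fragment fail with a
  parse error rather than silently returning wrong answers.
* Entailment is materialised, not incremental: after adding triples,
  re-run the entailment functions (they are idempotent, so re-running is
  always safe).
* The Turtle reader covers the subset the writer emits (prefixed names,
  `a`, `;`/`,` lists, typed literals) — not blank nodes or collections,
  which the models never use.
* All graphs are in-memory tibbles; the design targets desk-scale
  integrated models (~10^5–10^6 triples), not warehouse-scale stores.

## A worked example

```{r example, eval = FALSE}
study <- simulate_study(synthetic_config(seed = 1))
graph <- semantic_model_from_study(study)

pathway_contrast_counts(graph, "GO:0006915", "GO:0008283")
run_sparql(graph, stored_query("pathway-contrast"))

tf <- study$tf$records$tf_id[1]
tf_regulated_high_counts(graph, tf) |> tidy()
```
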