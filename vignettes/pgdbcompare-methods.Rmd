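---
title: "Comparing pathway/genome databases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing pathway/genome databases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgdbcompare)
```

## The problem

A pathway/genome database (PGDB) asserts, for one organism, a network of
genes, proteins, enzymatic reactions, compounds and pathways. When two PGDBs
exist for the same organism they typically rest on different annotation
pipelines, and a biologist choosing between them needs two kinds of
evidence: how *accurate* each resource's enzyme-function assignments are,
and how the resources' *content* differs. `pgdbcompare` computes both from a
shared entity model, and ships a synthetic-data generator that makes every
stage verifiable against planted truth.

## Gold-standard construction

The accuracy benchmark is a gene-level gold standard of Enzyme Commission
(EC) labels with experimental or manually reviewed support, built in four
steps:

1. **Source merge.** Two protein-level annotation tables — one manually
   reviewed, one experimentally verified — are unified. Cross-links re-key
   experimental accessions to their reviewed counterparts; the merge is the
   set union over (accession, EC label) pairs with provenance tags unioned
   per pair. An experimental accession linked to two distinct reviewed
   accessions is an error rather than a silent choice, keeping the merge
   auditable.
2. **Alignment filtering.** Source proteins are matched to the organism's
   translated gene models through alignment hits filtered at
   `percent_identity >= 96` and `evalue <= 1e-20`. Both bounds are
   *inclusive*: a hit exactly on a cutoff passes. These thresholds are the
   ones conventionally used to transfer curated annotations across
   essentially identical sequences; they are parameters of `filter_hits()`.
3. **Top-hit selection.** "Top scoring" is interpreted as highest bitscore
   (bitscores are length-normalized, unlike raw e-values); ties break by
   lowest e-value, then lexicographically smallest subject identifier, so
   the mapping is reproducible under any input ordering. Queries whose top
   hit fails the filters are dropped entirely rather than re-examined
   against weaker hits.
4. **Isoform consolidation.** Labels attached to alternative
   transcript/protein products of the same gene are unioned into one
   gene-level set. Consolidation can only merge labels, never invent them,
   so the gold annotation count is bounded by the number of merged
   (accession, label) pairs.

Only EC labels enter the gold standard; GO terms describe annotation
*coverage* in the overlap analysis but never accuracy.

## Scoring rules

Evaluation is restricted to gold-standard genes. For gold gene $g$ with gold
label set $G(g)$ and predicted set $P(g)$:

$$\mathrm{TP} = \sum_g |P(g) \cap G(g)|,\quad
  \mathrm{FP} = \sum_g |P(g) \setminus G(g)|,\quad
  \mathrm{FN} = \sum_g |G(g) \setminus P(g)|$$

with $P(g) = \emptyset$ when $g$ is absent from the resource's gene
universe — the *missing-gene rule*, which charges a resource for every gold
label of a gene it does not contain. Precision, recall and F-measure follow
the standard formulas, with zero denominators yielding 0.

Three design choices deserve comment:

- **No true negatives.** A true negative would require knowing that a
  function is experimentally ruled out, which annotation databases do not
  record; predictions on genes without gold annotations are therefore
  unscorable and contribute nothing. This is also why FP is only counted on
  gold genes: it is the only reading under which TP + FN equals the gold
  annotation count, an identity the package enforces as a *conservation
  check* and surfaces as a diagnostic when externally supplied counts
  violate it.
- **Exact label matching.** EC labels are compared by exact four-field
  string equality after normalization; `2.7.7.-` matches only `2.7.7.-`,
  not `2.7.7.7`. Hierarchical partial credit is deliberately out of scope:
  it requires a weighting scheme the benchmark does not define, and exact
  matching is the conservative default.
- **Full-precision internals.** Metrics are computed and stored at full
  precision; the two-decimal rounding seen in print methods is display
  only.

Merging two prediction sets takes the per-gene label union and the union of
gene universes, which makes TP monotone non-decreasing and FN monotone
non-increasing under merging — a property the tests check against
brute-force enumeration.

## Content overlap

Cross-resource matching is by exact shared frame identifier. This is
justified when both resources import reactions, compounds and pathways from
the same reference encyclopedia (MetaCyc-style identifiers); name- or
structure-based compound reconciliation (stereochemistry, protonation
states) is explicitly out of scope. Per entity class:

- **Genes** are compared over *annotated* genes only (≥ 1 GO term, or a
  protein catalyzing ≥ 1 reaction), since one resource may list the whole
  gene complement while the other restricts itself to enzyme-coding genes.
- **Proteins** are compared over reaction-mapped proteins (≥ 1 catalyzed
  reaction); spontaneous reactions map nothing.
- **Compounds** are compared over small, non-elemental molecules; the kind
  is an explicit slot (`small-molecule` / `macromolecule` / `element`)
  because the artifact does not ship a compound ontology to infer it from.
- **Reactions and pathways** are compared over all identifiers.

Reactions partition into shared / unique-to-A / unique-to-B, and each
partition is summarized by top-level EC class. Class 7 (translocases) is
accepted and reported as its own category even though older resources
predate it; reactions without an EC number (pending EC review, hypothetical
enzymes, or non-enzymatic transport) count as `unclassified`. The three
partition totals always sum to $|R_A \cup R_B|$.

## The flat-file dialect

PGDBs are exchanged in a minimal, faithful subset of the BioCyc
attribute-value format: one `SLOT - VALUE` per line, records terminated by
`//`, repeated slots accumulating into sets, continuation lines beginning
with `/`, `#` comments, UTF-8 with Unix or Windows line endings.
Identifiers are case-sensitive and matched exactly. A record without a
`UNIQUE-ID`, or a duplicate `UNIQUE-ID` within a file, is an error naming
the file and record index; unknown slots are skipped with a warning; and
unresolved cross-references are *collected as diagnostics* on the parsed
object rather than dropped, so referential integrity is checkable
(`check_references()` returns empty exactly when every reference resolves).
Writing sorts records and set values, which makes write→parse a fixed point
and enables byte-level reproducibility tests.

## The synthetic-data generator

`generate()` emulates the statistical structure of a real resource pair at
desk scale. Defaults (all tunable through `synthesis_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 5,000 | organism-wide gene pool; large enough for stable structure, small enough to run in seconds |
| `mean_isoforms_per_gene` | 1.6 | observed splice-variant rate in the reaction-centric maize resource |
| `go_fraction_a` / `b` | 9/9142, 0.531 | GO coverage of the two published resources |
| `reaction_map_fraction_a` / `b` | 0.991, 0.198 | reaction-mapping coverage of the two published resources |
| `entity_overlap` | gene 0.70, compound 0.70, reaction 0.60, pathway 0.65 | reaction and pathway fractions follow the published Venn counts; gene and compound overlap are unpublished, fixed once at a plausible 0.70 |
| `n_gold_genes`, `mean_labels_per_gold_gene` | 1,450, 1475/1450 | the published gold standard: 1,475 annotations across 1,450 genes |
| `planted_precision` / `recall` | a: 0.86/0.90, b: 0.74/0.84 | the published performance of the two resources |
| `missing_gene_fn` | a: 86, b: 2 | the published counts of missing-gene false negatives |
| `ec_class_weights` | published per-class reaction totals, normalized | class mix of drawn EC numbers |

Isoform counts are drawn as $1 + \mathrm{Geometric}(1/m)$ so the mean is
`mean_isoforms_per_gene`; the shifted-geometric choice is internal and
echoed in the config output. The gold-standard size is fixed to
`round(n_gold_genes * mean_labels_per_gold_gene)` exactly (one label per
gene plus randomly placed extras) so exact confusion counts can be planted.

**Counts are planted by construction, not sampled.** For each resource the
generator fixes TP/FP/FN (either from `planted_counts` or derived from the
planted precision/recall), then *chooses* which gold labels to copy into the
predictions, which to withhold, which genes to omit from the universe
(single-label gold genes placed in the other resource's unique gene region,
realizing the missing-gene FN count exactly), and draws corrupted labels for
the false positives. Entity overlap is likewise realized by assigning
identifiers to shared/unique regions, with shared reactions referencing only
shared compounds so both resources pass referential integrity. Every planted
quantity is recorded in an `expected` ledger, and the primary test harness
asserts that the full pipeline — including a round trip through flat files —
recovers the ledger *exactly*. Infeasible configurations (e.g. planted
recall exceeding what the missing-gene annotations allow) are rejected with
an error.

What the generator does **not** emulate: real sequences and chemistry,
MetaCyc's ontology, hierarchically related EC labels, correlated annotation
errors, and compound identity drift between resources. Passing tests
therefore demonstrate the correctness of the bookkeeping — the set algebra,
counting rules and formats — on data with realistic shape, not the accuracy
claims of any real resource.

All randomness flows from the single config seed; `generate_hits()` draws
its own stream from an offset of the same seed so hits are identical whether
generated standalone or as part of `generate()`. Regenerating with the same
config yields byte-identical files.

## Numerical and degenerate-input choices

- Metrics: 0/0 is defined as 0 for precision, recall and F.
- `normalize_ec()` pads missing trailing EC fields with `-`, strips an
  optional `EC-`/`EC ` prefix, accepts classes 1–7, and is idempotent;
  malformed labels are errors, not warnings.
- Top-hit ties break deterministically (bitscore, then e-value, then
  subject id).
- Venn and matrix outputs sort identifiers lexicographically, making every
  serialization deterministic.
- An empty directory parses to an empty PGDB; empty hit sets filter to
  empty; `ec_distribution(character(0))` is the all-zero distribution.

## Problem sizes used in validation

The test suite exercises the full pipeline at the default 5,000-gene scale
(one end-to-end run, a few seconds) and uses 300–500-gene configurations
elsewhere; the brute-force scoring oracle runs on 1,000 random gene/label
draws. The acceptance script repeats the 5,000-gene end-to-end run under the
caller's seed.

## Known limitations

- Entity matching assumes shared identifier namespaces; resources built on
  different reference encyclopedias would need a reconciliation layer.
- The confusion model has no true negatives, so specificity-style metrics
  are undefined by design.
- The flat-file reader covers the slots this analysis needs, not the full
  BioCyc schema (no regulation, citations or evidence codes).
- Published merged-resource confusion tables do not always satisfy the
  TP + FN conservation identity; the package reports such discrepancies as
  diagnostics rather than reproducing them.
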