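---
title: "Harmonizing pathway databases into unified BEL-style graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing pathway databases into unified BEL-style graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beltway)
```

## The harmonization model

KEGG, Reactome and WikiPathways encode comparable biology in three
unrelated schemata (KGML, BioPAX Level 3, GPML) with three unrelated
identifier and relation vocabularies. `beltway` treats harmonization
as a three-stage pipeline with one shared intermediate representation:

1. each parser emits a `source_pathway` — entities with raw source
   types and candidate cross-references, pairwise interactions with
   raw relation labels, and reified reactions;
2. normalization resolves each entity to one prioritized identifier;
3. conversion maps raw types/relations into a closed unified
   vocabulary, producing a provenance-tagged directed multigraph.

The target model deliberately mirrors the Biological Expression
Language: nine node classes (gene, rna, mirna, protein, abundance,
complex, family, bioprocess, reaction) and twelve relation types, of
which `increases`/`directly_increases` carry polarity +1 and
`decreases`/`directly_decreases` polarity −1. A node's identity is its
class plus its resolved `prefix:identifier` plus its sorted
modification tokens. Two modelling commitments matter here:

* **Labels never participate in identity.** Display names vary freely
  across databases; identifiers are the harmonized handle. Entities
  that could not be normalized keep a database-native prefix, so
  unmapped entities from different databases can never spuriously
  merge.
* **Modifications do participate in identity.** Curators record
  species such as phosphorylated or spliced forms as distinct
  entities ("p-y641-stat6"); a modified protein is therefore a
  distinct node until an analysis explicitly collapses it.

Reactions are reified as nodes joined to their participants by
`has_reactant`/`has_product` edges, with catalysts attached by
`increases` edges. The reaction node's identifier is a deterministic
31-bit digest of its sorted participant keys, so the same conversion
written by two databases unifies on merge. Reversible reactions are
emitted once, annotated in the label, rather than duplicated per
direction.

## Identifier normalization

Normalization walks a per-modality namespace priority list: genes and
gene products target HGNC, falling back through UniProt, NCBI Gene and
Ensembl; metabolites target ChEBI then PubChem; miRNAs target miRBase.
Cross-references may reach a prioritized namespace *transitively*
through a mapping table — e.g. a KEGG gene accession maps to NCBI Gene
and from there to HGNC. Transitivity is capped at **two hops**: that
is exactly the depth the intermediate-namespace route requires, and
the cap (together with a visited set) makes resolution total and
cycle-safe on arbitrary tables. The highest reachable namespace wins;
ties between cross-references are broken by their order in the source
file, and disagreements are logged. Entities with no route retain
their native identifier; entities with no cross-reference at all are
minted a synthetic `<database>.local` identifier from their label
slug, which keeps them countable without inventing equivalences.

Mapping tables are plain four-column TSVs rather than live
web-service lookups, so the whole pipeline builds and tests offline;
the loader accepts drop-in replacements with full-coverage tables.
miRNAs need special handling because GPML and KGML type them as
generic gene products: an entity is classed `mirna` when it carries a
miRBase cross-reference or its lowercase label matches the
`-mir-`/`-let-` nomenclature pattern.

## Relation and class mapping

The bundled class and relation maps (`default_class_map()`,
`default_relation_map()`, dumped by the CLI `show-maps` command) are
reconstructions and are user-overridable via three-column TSVs. Two
choices deserve explanation:

* **KEGG gene entries default to `protein`.** KGML signalling arrows
  act between gene products. A `genes_as = "genes"` switch exists, and
  the choice is invisible to the similarity layer because the *genes*
  modality pools gene, RNA and protein nodes anyway.
* **Exactly four KEGG subtypes map to SKIP** — *hidden compound*,
  *state change*, *dissociation*, *missing interaction*. These are
  non-causal bookkeeping labels with no unified-edge equivalent.
  Skipped interactions are dropped loudly: tallied per label,
  reported by `skipped_relations()`/`count_skipped()`, and fatal
  under `--strict`. Any raw type or relation *absent* from the maps is
  a hard error, which forces the maps to stay total as parsers evolve.

KGML relations mediated by a compound entry are rewritten into two
interactions through the mediator (source → compound → target,
labelled `compound_mediated`) so the mediator survives as a node
instead of being discarded. KEGG modification subtypes
(phosphorylation, ubiquitination, ...) become `directly_increases`
(`directly_decreases` for dephosphorylation) with the subtype retained
in edge provenance; KGML does not state the resulting residue state,
so no node-level modification is fabricated.

For WikiPathways we parse GPML, the native per-pathway curation
format, rather than the RDF dump: it is self-contained and removes a
triple-store dependency, with identical information content for the
subset used (DataNodes, Interactions, Groups, one level of Anchor
indirection). For Reactome we parse the BioPAX Level-3 RDF/XML export
directly as XML over a fixed class subset; sub-pathway hierarchies are
not recursed — one file is one pathway, matching the granularity at
which pathways are compared. Canonical-pathway filtering is a
caller-supplied allowlist, not inferred.

## Comparison statistics

Similarity uses the Szymkiewicz–Simpson overlap coefficient
S(X,Y) = |X∩Y| / min(|X|,|Y|), computed over *molecular entity sets*:
group (complex/family) and reaction nodes are excluded, and
gene/RNA/protein nodes are collapsed to gene level with modifications
stripped before set construction (a flag disables collapsing for
sensitivity analysis). Collapsing is what makes the comparison fair —
databases use gene, RNA and protein forms of the same entity
interchangeably. The default similarity set includes all modalities
(genes, metabolites, miRNAs, biological processes); a modality filter
restricts it.

Numerical conventions:

* S is defined as **0 when either set is empty** (min would divide by
  zero). An empty set is a real situation — a source file with no
  convertible content — and the convention gives the index its
  natural floor of 0.
* The three-way index sums its three coefficients **in sorted order**
  before dividing by three, which makes it exactly permutation
  invariant in floating point, not merely up to rounding.
* Shared/partial/exclusive ratios partition the union, so they sum to
  1 by construction.

Consensus detection considers every ordered node pair with two or
more polar edges from two or more distinct source pathways, and, by
default, treats `increases`/`directly_increases` as the same polarity
(the causal claim agrees even when directness differs); a
relation-exact mode requires identical relation types.

## The fixture generator

`generate_trio()` writes one synthetic pathway as real KGML, GPML and
BioPAX text — the actual parser code paths are exercised, not mocks.
A plan fixes how many entities are shared by all three databases,
by each pair, and exclusive to each; entities are genes from a
synthetic HGNC-like namespace, and each dialect deliberately carries a
*different* identifier type (KEGG accessions, Entrez Gene ids, UniProt
accessions) tied together by a generated mapping table, so the
normalization cascade (including the two-hop KEGG → NCBI Gene → HGNC
route) is genuinely on the critical path. Each file carries one
positive-polarity relation per consecutive entity pair; a
`contradict` option plants exactly one opposite-polarity duplicate of
a shared edge between KEGG and WikiPathways, making
consensus/contradiction detection testable with a known answer.

Because the planned counts determine the entity sets exactly, the
similarity index and overlap ratios of the converted trio have
closed-form expected values, giving the whole
parse → normalize → convert → collapse → compare pipeline an exact
end-to-end oracle (equality to the float, no tolerance). Default plan
sizes are a handful of entities per region — the regime in which every
region of the three-set Venn partition is populated — and tests sweep
randomized plans with region counts 0–4; the acceptance script runs 20
such plans plus a fixed reference plan. Generation is deterministic
given the plan seed, down to identical bytes.

What the generator does **not** emulate: realistic pathway topology
(degree distributions, hub structure), mixed modalities within one
file, curation noise such as malformed cross-references, or the scale
of real exports (hundreds of nodes). Passing the end-to-end oracle
therefore demonstrates correctness of the harmonization and
comparison machinery, not robustness to every curation idiosyncrasy
found in the wild; the parser unit tests cover the known
idiosyncrasies (multi-accession entries, anchors, entity sets, groups,
missing attributes) individually.

## Serialization

Node-link JSON is the canonical interchange form (portable, diffable,
and the natural input for web visualization); write → read is the
identity on node-key sets and edge multisets, and all writers iterate
in sorted order so output is byte-stable — golden-file tests are
possible. BEL script export is write-only (parsing BEL is out of
scope), and GraphML carries class, namespace and provenance as typed
attributes for downstream tools.

## Known limitations

* BEL namespace resource files and full BEL 2.0 statement semantics
  (activities, translocations, compartments) are not modelled.
* Only human identifier spaces are prioritized; cross-species
  orthology mapping is out of scope.
* The bundled class/relation maps are overridable reconstructions;
  users with authoritative mapping tables should supply them.
* Entity counts and similarity indexes of real database exports
  depend on the snapshot date of those exports and are not reproduced
  by this package's tests; the comparison layer is validated on
  fixtures with analytic expectations instead.
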