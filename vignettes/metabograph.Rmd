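---
title: "Building and querying integrated biochemical knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and querying integrated biochemical knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabograph)
```

## The data model

`metabograph` represents biochemical knowledge as a labelled property
graph with four node labels — **Organism**, **Enzyme**, **Reaction** and
**Chemical** — connected by directed, typed relationships. Organisms form
a taxonomy tree through `is_a` edges and are linked to the enzymes they
express (`expresses`); reactions are linked to their catalysts
(`catalysed_by`) and to their chemical participants (`has_reactant` /
`has_cofactor`, carrying a signed integer `stoichiometry`: negative for a
consumed species, positive for a produced one); chemicals are related to
one another through the nine ontology relation types of a chemical class
hierarchy (`is_a`, `has_functional_parent`, conjugate acid/base pairs,
tautomers, enantiomers, and so on).

Node keys follow the unique identifier of each domain: taxonomy id for
organisms, UniProt accession for enzymes, and database ids for reactions
and chemicals. The store is in memory, iterates in insertion order (so
exports are reproducible), and deduplicates relationships on the full
(endpoints, type, properties) tuple — two edges that differ only in their
`source` property are deliberately kept separate, preserving provenance.

The motivation for this shape is query-ability *across* domains: a single
pattern can connect a taxon, the enzymes its genome encodes, the
reactions they catalyse and the chemistry those reactions touch, which is
exactly the kind of question that is painful to answer against separate
single-domain databases.

## Sources, namespaces and merging

Graphs are populated from miniature flat files in five frozen dialects
(`build_graph()`): an NCBI-style taxonomy dump pair (`nodes.dmp` /
`names.dmp`), MNXref-style chemical and reaction property tables, a
simplified ChEBI-style ontology export (compounds, relations, data,
names), and a UniProt-like protein table whose `reaction_xrefs` column
carries the enzyme-reaction links that KEGG and Rhea provide in the wild.
Real release layouts of these databases drift over time; freezing a
documented dialect keeps the parsers testable without any download while
accepting the same information content.

Each source names external databases differently (`"KEGG COMPOUND
accession"` in one export, `"kegg"` in another).
`normalize_namespace_key()` maps every token to a canonical
identifiers.org key, with the node-label context resolving ambiguous
tokens (`kegg` means `kegg.compound` for a chemical but `kegg.reaction`
for a reaction). The mapping is total over what the bundled parsers emit
and extensible through the build config; an unknown token raises an
error rather than passing through silently, because a silently unmapped
namespace would quietly disable merging for that source.

`merge_entities()` merges two same-label records exactly when they share
at least one (namespace, accession) pair, transitively, via union-find.
Name equality is deliberately *not* a merge key — chemical synonyms are
far too ambiguous. Property conflicts are resolved by source precedence
(default `chebi > mnxref` for chemicals, `mnxref > kegg` for reactions;
ChEBI is the curated ontology, which is why it outranks an aggregator),
and every losing value is logged in the merge report rather than
discarded invisibly. Structure-line conflicts (InChI) are treated as
ordinary logged conflicts, not merge blockers. After the merge no
accession appears on two nodes, and re-merging the output is the
identity.

## Cofactor annotation

Reaction-chemical edges start as `has_reactant` and are relabelled
`has_cofactor` by `annotate_cofactors()` under two rules:

* **low mass** — monoisotopic mass strictly below 44 Da (protons, water;
  note that CO2 at 43.9898 Da falls below the strict threshold and is
  therefore classified as a cofactor — this edge case is retained
  as-written rather than special-cased);
* **frequent pairs** — unordered pairs that co-occur with opposite signs
  in at least `min_pair_count` reactions (the ATP/ADP pattern), computed
  at load time by `detect_frequent_pairs()`. "Frequent" is not a sharply
  defined notion; it is operationalised here as
  `max(2, ceiling(0.05 * n_reactions))`, which captures the canonical
  currency couples on small networks without relabelling ordinary
  metabolites. Pair relabelling applies only inside reactions where both
  pair members appear with opposite signs, so a lone ATP substrate is
  not hidden from pathway search; both members of a pair are relabelled.

Annotation only retypes edges: stoichiometries and the total
reaction-chemical edge count are invariant, which the tests assert.

## Reaction balancing

A reaction is balanced when every element count and the total charge,
weighted by signed stoichiometries, sum to zero (`verify_balance()`; a
participant without formula or charge yields the *unknown* signal, never
`FALSE`). `balance_reaction()` repairs unbalanced reactions by searching
for new integer stoichiometries under three hard constraints: existing
participants keep their side, never drop to zero, and stay within a
maximum coefficient (default 20); a configurable set of addable species —
protons and water by default, the species most often omitted from source
reaction definitions — may be introduced on either side.

The objective is lexicographic minimal perturbation: first minimise the
total deviation from the original stoichiometries, then the total amount
of added species, breaking remaining ties in favour of protons over
water and smaller coefficient sums. "Respecify incorrect
stoichiometries" is read as "change as little as possible"; a repair
that rewrites the whole reaction when adding one proton suffices would
not be a correction but a different reaction.

Because participant lists are short, the search is exact: iterative
deepening over the deviation budget, with the added-species coefficients
obtained by an exact linear solve (the proton/water composition matrix
has full column rank, so the additions are uniquely determined by each
candidate stoichiometry vector; degenerate addable sets fall back to a
bounded grid). A search budget (default 200,000 candidate vectors)
bounds the worst case; a reaction that exhausts the budget or the
coefficient bound is reported `unbalanceable`. Tests verify the solver's
optimum against full-grid enumeration on all generated cases with up to
five participants and coefficients up to three.

Chemicals with generic formulas (R-groups, polymeric `n`) poison the
whole reaction, which is retained with status `unknown` rather than
being silently treated as balanced or dropped.

## Queries

* `reaction_context()` — does a reaction occur in an organism? Returns
  the subgraph of the reaction, its chemicals, enzymes catalysing it
  that the organism expresses, the organism and its taxonomy parent, and
  chemical-chemical edges among the returned chemicals; an empty
  subgraph means "no".
* `descendant_chemicals()` — transitive closure below a named chemical
  class over all nine ontology relation types, optionally restricted to
  rows with a concrete molecular formula (class nodes such as "flavans"
  carry none). Cycles terminate through a visited set; results are
  distinct on (name, formula, chebi, inchi).
* `taxon_metabolome()` — chemicals reachable through the pattern
  Chemical ← Reaction → Enzyme ← Organism → parent taxon, with stored
  monoisotopic mass strictly inside an exclusive window. Cofactor edges
  are excluded so currency metabolites do not masquerade as metabolome
  members. The `is_a` hop is one level by default (matching the pattern
  as a strain-to-species hop); `transitive = TRUE` follows deeper
  hierarchies.
* `find_pathways()` — shortest alternating chemical/reaction pathways
  from any host-native metabolite (a chemical attached by
  `has_reactant` to a reaction catalysed by a host-expressed enzyme —
  either sign, with a `produced_only` switch) to a target chemical.
  Traversal uses `has_reactant` edges only, ignores their stored
  direction, and instead enforces reactant-to-product directionality by
  the sign rule: every pair of consecutive edge stoichiometries along
  the path has a negative product, both where edges meet at a reaction
  and at an intermediate chemical. Paths are simple — with repeated
  nodes allowed, "shortest under sign alternation" would be
  ill-defined — and capped at `max_len` reactions (default 8). All
  global-minimum-length pathways are returned, ordered
  lexicographically by node sequence for determinism.
* `pathway_enzymes()` — every (catalysing enzyme, expressing organism)
  pair for every reaction on a set of pathways, with empty cells for
  orphan reactions and unexpressed enzymes, supporting the "which
  organisms could donate this step" question.

Each query has a brute-force counterpart in the test suite (matrix-power
closure, exhaustive path enumeration, full per-node scans) and is
required to agree with it on small graphs.

## Synthetic data

`generate_fixture()` writes all five source dialects with known ground
truth. Its chemistry is built for exact verifiability: pool chemicals
form hydration ladders, each step adding H and O and lowering the charge
by one, so that every generated reaction `X(k) + H2O = X(k+1) + H(+)` is
balanced by construction. Corruption for the balancing tests strips the
produced proton — a repair whose unique minimal fix is known. Each
ladder edge is used by at most one reaction so the frequent-pair rule
never relabels backbone metabolites, keeping cofactor ground truth
(water and protons only, via the mass rule) exact. A configurable
fraction of chemicals is emitted in both the MNXref and ChEBI files
under linked accessions, giving merge tests exact expected node counts.
The default scale (10 organisms, 12 enzymes, 12 reactions, 20 chemicals)
keeps every fixture build well under a second while still exercising
merging, annotation and balancing together.

Two further generators stand in for result sets whose originals are
distributed as supplementary material of the study this design follows:
`synthetic_flavonoid_ontology()` (by default 1081 formula-bearing
species under a "flavonoid" root, plus formula-less class layers and an
unrelated decoy branch) and `synthetic_strain_metabolome()` (by default
111 metabolites with masses strictly inside (400, 500) Da wired under
taxon 562, plus out-of-window, boundary and cofactor-linked decoys).
They are synthetic: what passing tests show is that the closure,
filtering and graph-pattern machinery recovers exactly the planted rows
from among the decoys — not that the package reproduces curated
third-party content. Likewise, the fixture generator emulates structure,
not biology: real sources bring malformed rows, richer ontologies, and
name/structure conflicts at far higher rates than the generator plants.

## Numerical and degenerate-input choices

* Monoisotopic masses come from a bundled, versioned
  most-abundant-isotope table; computed masses are compared at 1e-4 Da
  in tests. Stored source masses are kept verbatim and never overwritten
  from the formula (aggregator databases routinely print the
  neutral-species mass next to an ionised formula; both facts are worth
  retaining).
* Formula parsing accepts plain element-count strings only; generic
  tokens (R-groups, `X`, `n`-repeats, `*`, parentheses) raise a
  dedicated condition so callers can demote the record to a class node,
  while genuinely malformed strings are hard errors.
* Degenerate equations (`1 A = 1 A`) drop net-zero participants with a
  warning, leaving an empty participant list; empty participant lists
  are vacuously balanced.
* Balance verification uses an absolute tolerance of 1e-9 on integer
  arithmetic carried in doubles.
* The bulk CSV dialect uses batch-importer header conventions (`:ID`,
  `:LABEL`, `:START_ID`, `:END_ID`, `:TYPE`, `string[]` arrays with `;`
  delimiters), RFC 4180 quoting, UTF-8, LF endings, and key-sorted rows
  so identical graphs export byte-identically.

## Known limitations

* Chemical identity is cross-reference-based; structure-based merging
  (InChI-key canonicalisation) is a natural extension but is not
  implemented.
* Balancing does not model pH-dependent charge states or polymers, and
  never moves a participant across sides.
* The taxonomy validator enforces a single root and acyclic parents;
  multi-rooted forests are rejected rather than repaired.
* The CLI and bulk export realise the batch-import surface of a property
  graph engine; no live database server is contacted or required.

## Problem sizes used in the shipped checks

Fixture builds use the default scale above; pathway-search equivalence
runs on fifty random networks of 25 chemicals and 25 reactions at
`max_len = 8`; balancing equivalence enumerates cases with up to five
participants and coefficients up to three; the ontology and metabolome
stand-ins run at their default sizes (1081 and 111 planted rows). These
sizes were chosen so that the brute-force oracles stay exact and the
whole suite completes in well under a minute on one core.
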