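---
title: "Comparing development stages across plant species: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing development stages across plant species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagecomp)
```

# The problem

Gene-expression annotations tied to development-stage ontology terms make it
possible to ask which genes are active during which interval of a plant's
life, and — because stage terms are species-neutral — to compare those gene
sets between species with very different developmental anatomy, such as a
dicot (Arabidopsis) and a monocot (maize) during embryogenesis. `stagecomp`
implements that comparison workflow end to end: ontology reasoning over
typed stage relations, evidence-filtered annotation handling, reciprocal
best hit (RBH) homolog clustering to bridge gene namespaces, overlap and
uniqueness statistics, and slim-mapped term enrichment with cross-set
comparison.

# Stage-ontology reasoning

A `stage_graph` stores terms and typed edges. Six relations take part in
reasoning:

* `is_a` — the primary hierarchy. Shorter, more specific stages are
  subclasses of longer, more general stages, so an annotation search on a
  grouping stage can collect annotations from all of its sub-stages
  (the true-path rule, applied by `genes_for_stage(propagate = TRUE)`).
* `part_of` — links a stage of one structure to the stage of a containing
  structure. Its closure is exposed via `stage_ancestors()`, but annotation
  propagation uses `is_a` only: the subclass hierarchy is what carries
  stage annotations, and propagating across `part_of` would mix stages of
  different structures.
* `precedes` / `preceded_by` — temporal order. Both relations are
  transitive, and every stored edge is materialised together with its
  inverse at parse time, because downstream reasoning uses whichever
  direction is convenient. `preceded_by_closure()` walks backward in time;
  `temporal_sort()` produces a stable topological order in which terms with
  no ordering relation keep their input order — many branches of real stage
  ontologies carry no temporal edges at all, and a stable sort keeps those
  regions predictable.
* `has_participant` / `participates_in` — stage-structure participation,
  read under the every/some rule: `structure participates_in stage` means
  every such structure exists during some such stage, which licenses
  inferring a stage association from a structure association but *not* the
  converse. `infer_stage_structure_links()` is therefore one-hop and
  direction-asymmetric; it records the edge used as provenance and never
  chains inferences unless re-applied.

Predicates outside these six are preserved on the graph (and survive a
write/parse round trip) but are ignored by reasoning — real ontology files
contain relations this package takes no position on. Obsolete terms are
excluded from all closures, the standard treatment for OBO vocabularies.
`validate_stage_graph()` reports cycles in the `is_a` and `precedes`
subgraphs, dangling edge endpoints, missing temporal inverses, self-edges
and malformed identifiers without modifying the graph.

# Annotations and evidence

`.assoc` files are read as GAF 2.x: tab-delimited, `!` comments, 15–17
columns (extras ignored). Malformed lines are counted in a rejects report
rather than silently dropped. The object identity used throughout is the
gene/gene-model identifier in column 2, not the symbol.

Evidence filtering defaults to the two experimental codes that dominate
stage-annotation data — Inferred from Expression Pattern (IEP) and Inferred
from Direct Assay (IDA) — and an empty code set is an error rather than an
implicit "keep everything". All overlap and uniqueness statistics operate
on *deduplicated identifier sets* of direct annotations, without true-path
propagation: per-stage downloads are compared exactly as annotated, and
distinct-gene semantics is what makes the per-stage unique percentages
reproduce from distinct-gene totals.

# Homolog clustering

Cross-species comparison happens in homolog-cluster space. The input is a
precomputed BLAST-like similarity table (no aligner is bundled; fixtures
and real pipelines both supply scores). The steps:

1. **Mutual-overlap filter** (`filter_hits`): a hit survives only if at
   least `min_overlap_frac` (default 0.50) of *both* sequences is covered
   by the alignment, boundary inclusive.
2. **Reciprocal best hits** (`reciprocal_best_pairs`): `(a, b)` is a seed
   pair iff each is the other's highest-scoring cross-species hit. Multiple
   hits per ordered pair collapse to the maximum score; if only one
   orientation is present the score is mirrored (symmetric-score mode, the
   default — whether the original analyses required both BLAST directions
   is not documented, and mirroring makes the result orientation-free).
   Score ties break toward the lexicographically smaller id, which makes
   the output deterministic.
3. **In-paralog assignment** (`build_clusters`): an unseeded gene `g` joins
   the cluster seeded by `(a, b)` iff `g`'s best cross-species hit is `b`
   and `score(g, b) >= score(a, b)`; conflicts resolve to the highest
   qualifying score, and every gene lands in at most one cluster. This is
   a deliberately reduced InParanoid-style rule: no bootstrap support, no
   resolution of overlapping clusters beyond best-score assignment.

The synthetic similarity generator is designed so recovery is guaranteed by
construction: planted pair scores (200–400) strictly exceed all noise
scores (40–120), and in-paralogs are emitted with a within-species hit up
to 10% above the seed score plus a cross-species hit *tied exactly* at the
seed score. A cross-species in-paralog hit strictly above the seed score
would displace the planted pair as reciprocal best, so the tie — resolved
by the lexicographic rule, with in-paralog ids constructed to sort after
their seed — is what lets the planted pair stay the seed while the
in-paralog still satisfies the join rule at equality.

# Overlap and uniqueness statistics

The comparison statistic is

$$\%\,\text{overlap} = \frac{|A \cap B|}{(|A| + |B|)/2} \times 100,$$

shared identifiers over the average set size. It is symmetric, 100 exactly
when the sets are equal (and nonempty), 0 exactly when disjoint. Within a
species it is computed on gene ids (and optionally cluster ids); between
species only on cluster ids, and `cross_species_overlap()` refuses
gene-space input. Per-stage uniqueness is the complement of the union of
all other stages; percentages are reported to 2 decimals with half-up
rounding to match how such tables are conventionally printed (base R's
`round()` is half-even). Stages with fewer than 50 identifiers trigger a
warning — percentage statistics on tiny sets are unstable, and real
analyses exclude such species/stage combinations — with the threshold
configurable per map.

`contrast_sets()` encodes the four standard contrast recipes: the
early-not-late and late-not-early gene sets within one species, the
cross-species cluster difference back-converted into either species' gene
ids (two id conventions for the same cluster set), and the full reference
stage set.

# Term enrichment

`fisher_enrichment()` tests over-representation only (one-sided): the
p-value is the hypergeometric tail $P[X \ge k]$ with population size $N$,
$K$ population carriers and study size $n$, identical to the one-sided
Fisher exact test on the 2x2 table. Choices that needed fixing where
common tools are ambiguous:

* **`min_mapped` (default 5)** applies to the *study-set* mapped count:
  terms carried by fewer than 5 study genes are pruned as untestable before
  the family is formed.
* **Background**: supplied explicitly as a gene-to-term map; population
  genes with no mapping are excluded from $N$ and counted in an attribute
  rather than silently vanishing.
* **Adjustment**: Benjamini–Yekutieli step-up (`adjust_by`), with the
  $c(m) = \sum_{i=1}^m 1/i$ correction, valid under arbitrary dependence
  between term tests — term tests are strongly dependent through the
  ontology. The implementation delegates to `stats::p.adjust(method =
  "BY")`; the test suite pins it to the hand-evaluated formula and to
  dominance over Benjamini–Hochberg.
* **Slim mapping** (`map_to_slim`): each annotated term is replaced by its
  *minimal* slim ancestors — slim terms reachable via `is_a`/`part_of`
  that have no other reachable slim term below them — and a gene counts at
  most once per slim term. Genes whose terms reach no slim term are
  dropped and counted.

`seacompare()` cross-tabulates several enrichment results over the union of
tested terms and reports per-set significant counts plus the union and
intersection of the significant lists (tabular only; no graphics).

# Synthetic data: what it emulates and what it does not

The generators produce the three statistical structures the workflow
assumes, with a single integer seed per call and byte-identical output for
identical `(params, seed)`:

* `make_stage_ontology()` — an `is_a` hierarchy crossed with a linear
  `precedes` chain, always valid.
* `make_annotation_table()` — a shared core of `shared_frac` times the
  per-stage gene count annotated to every stage plus stage-specific
  remainders, mirroring the empirically high between-stage overlap
  (roughly 86–98% in real embryo-stage data) with small unique fractions.
  Evidence codes are drawn IEP/IDA/IEA at 0.60/0.25/0.15 so that evidence
  filtering has visible effect. The core is deterministic in size, so the
  realized overlap equals the request up to rounding of the core size.
* `make_similarity_fixture()` / `make_enrichment_fixture()` — planted
  ortholog pairs with guaranteed score margins (above), and a planted
  enriched term at a stated fold over a uniform background frequency
  (default 0.05), with the planted structure returned as a truth object
  and serialisable as a JSON sidecar.

These fixtures are presence/absence structures only. They do not simulate
expression levels, microarray noise, annotation bias between databases,
paralog-rich gene families, or the very uneven per-species annotation
depth of real repositories — so green tests demonstrate correctness of the
set arithmetic, clustering rules and statistics under the stated
assumptions, not robustness to those real-data pathologies. Stage
annotations also carry no level or direction of expression, which is why
no fold-change comparison exists in this package.

# Problem sizes and numerical choices

The test suite verifies the hypergeometric tail against exhaustive
binomial-coefficient enumeration for every valid count configuration with
$N \le 60$ (tolerance $10^{-12}$); clustering recovery over 50 seeded
fixtures of 20 pairs, 5 in-paralogs and 30 noise hits; overlap structure
over 20 seeded tables of 4 stages times 1,000 genes; and enrichment power
(planted 5-fold term, study size 200, detected at BY $\le 0.05$) over 100
seeds with a 500-seed null series for the false-positive rate. These sizes
were chosen as the smallest at which the binomial/hypergeometric
tolerances quoted above are meaningful. The acceptance script re-runs
smaller versions of the stochastic suites (20/10/50/200 seeds) alongside
the worked-example arithmetic.

Percent formatting is fixed at 2 decimals half-up; set operations are
performed on exact identifier sets, so no numerical tolerance enters
anywhere except the p-value computations.

# Known limitations

* Clustering supports exactly two species; no multi-species graphs, no
  synteny, no bootstrap confidence. The similarity "confidence cutoff"
  sometimes quoted alongside the 0.50 overlap rule is not a defined
  statistic and is not implemented; the overlap rule is the operative
  filter.
* No OWL/description-logic reasoning, no cross-ontology import resolution,
  and no retrieval from live annotation services: all inputs are local
  files.
* Annotation propagation is `is_a`-only by design (see above); users who
  want `part_of` closures can compute them explicitly with
  `stage_ancestors()`.
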