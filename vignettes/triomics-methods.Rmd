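---
title: "Methods: tripartite multiomics integration"
author: "triomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tripartite multiomics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

## Scope and model

`triomics` integrates three per-group lists of differential calls — genes,
proteins, metabolites, each with an up/down direction — into candidate
biomarker sets. It deliberately starts *after* differential calling: fold
changes and p-value thresholds belong to the upstream omics pipelines, and
only the resulting direction-labelled lists enter here. The treatment design
is a grid of doses and exposure times; each (dose, time) cell is a group,
rendered `"<dose>uM-<time>h"`.

The integration rests on three assumptions worth stating explicitly:

* **Concordance filter.** A gene/protein pair is biologically credible only
  when both layers move in the same direction in the same group. Magnitudes
  are not compared across layers — transcript and iTRAQ-style protein ratios
  are not on a common scale — so consistency is direction-only.
* **Pathway topology carries causality.** An enzyme-encoding gene is
  considered upstream of a metabolite when the metabolite is reachable in
  the pathway's directed reaction graph along a path whose *first* edge is
  catalysed by that gene. Multi-hop reachability is the default
  (`max_hops = Inf`): a reductase acting several reaction steps above a
  terminal catabolite still regulates its level, and requiring immediate
  adjacency would discard exactly such relations. `max_hops` exists for
  sensitivity analyses.
* **Co-occurrence, not enrichment.** A joint pathway needs only one pair
  gene and one differential metabolite of the group among its members. With
  desk-scale inputs per group, over-representation statistics would be
  powerless; counting pathways once per group keeps the two summary columns
  (joint / with-relation) interpretable and trivially satisfies
  relation-count ≤ joint-count.

## Identifier handling

Gene and protein identifiers are stored as given and compared
case-insensitively; the default gene→protein mapping pairs identifiers equal
under case folding (mouse convention *Rrm2* ↔ RRM2) and can be replaced by
an explicit one-to-one mapping file. Metabolites are matched by name:
lowercased, internal whitespace collapsed, no synonym resolution. This is a
deliberate limitation — name-based matching fails across vocabularies
(HMDB vs KEGG naming), and resolving that belongs to a curation step, not
this package. Contradictory calls (same entity, group, both directions) are
rejected at ingestion rather than resolved silently; duplicate concordant
calls collapse to the one with the largest |magnitude|.

## Knowledge base

A pathway is a membership set (genes, metabolites) plus directed reaction
edges `source → target` annotated with zero or more catalysing genes.
Reversible reactions are encoded as two opposed edges *in the data*; the
query code treats every edge as directed, keeping chemistry in the KB files
rather than in control flow. Edge endpoints must be pathway members, and
parallel edges merge with catalyst-set union. Cofactor/currency metabolites
(ATP, H2O, NAD) are intentionally absent from the bundled fixture graphs:
they would create meaningless shortcuts between otherwise distant reactions.

The bundled mini-KB is a hand-curated, coarse-grained transcription of seven
reference pathway maps (purine, pyrimidine, unsaturated fatty acid
biosynthesis, cysteine/methionine, amino/nucleotide sugar, porphyrin,
glycerophospholipid) containing just the species needed to realise the
worked example's relations, two joint-only pathways (glutathione, arginine
biosynthesis — their pair genes are members but catalyse no productive edge
toward a differential metabolite) and three decoy pathways. It is a test
fixture, not a KEGG mirror.

## Network construction and ranking

Each relation link (group, pathway, pair, metabolite) contributes three
undirected edges pair–pathway, metabolite–pathway, pair–metabolite. The same
entity seen in several groups becomes one node — the network is
group-agnostic, with provenance kept as a node attribute — because a pair
recurring across doses is stronger, not separate, evidence. Components are
ranked by (metabolites desc, pathways desc, pairs desc, smallest gene id)
and labelled A, B, …; metabolites outrank pathways because the candidate set
is ultimately a metabolite panel anchored by one pair. The final tie-break
on gene id is this package's choice, made so the ranking is a total order
and outputs are byte-reproducible. Candidates are all pairs and metabolites
of subnetwork A; an empty network yields an explicit empty candidate set.
Component finding is delegated to `igraph::components()`; the test suite
cross-checks it against an independent union-find oracle.

## Correlation analysis

Within each dose, Pearson *r* between the phenotype series (percent cell
proliferation, in (0, 100]) and three indicator series over the time points:
differential-metabolite count, joint-pathway count, relation-pathway count.
The strong/not-strong classification uses signed *r* > 0.8 by default;
`abs_r = TRUE` switches to |*r*|, useful when an indicator is expected to
*rise* as proliferation falls. With three time points per dose a p-value
would be meaningless, so none is computed. `pearson_r()` wraps
`stats::cor()` with explicit validation (equal lengths ≥ 2, nonzero
variance, result clamped to [−1, 1] with 1e-12-scale tolerance); tests
verify it against a longhand covariance/standard-deviation formula.

## Synthetic benchmark

`simulate_kb()` emits pathways as metabolite chains (length drawn from
`chain_length_range`, default 4–7, occasionally branched) with each
main-chain edge catalysed by its own gene. `simulate_tables()` plants
direction-consistent pairs on randomly drawn catalyst genes and relations on
metabolites genuinely downstream of them, then adds noise:

* noise genes and proteins use identifier pools disjoint from the KB and
  from each other, so they can never form pairs or joint hits;
* noise metabolites are rejection-sampled from KB metabolites *not*
  reachable from any planted pair gene of the same group (capped retries,
  hard error on exhaustion), so no unplanned relation can arise;
* the recorded truth is the *closure* of the emitted records: if a planted
  metabolite happens to sit downstream of two planted pairs in one group,
  both relations are truth.

`p_direction_flip` breaks pair consistency with the given probability;
flipped pairs stay in the emitted tables as decoys but leave the recoverable
truth. The default design (2 doses × 3 times, 6 pathways, 4 pairs, 6
relations, 5 noise calls per layer) mirrors a small exposure study. The
generator emulates the *combinatorial* structure of multiomics screens —
direction labels, group assignment, pathway reachability — and nothing of
their measurement process: no intensities, no missingness, no correlated
noise, no many-to-many gene–protein mapping. Perfect recovery on noise-free
instances therefore validates the pipeline's bookkeeping, not its robustness
to real measurement error.

## Numerical and degeneracy choices

* All orderings are made total (groups by dose then time; catalogue by
  group, pathway, gene, metabolite; hits by relation count then pathway id),
  so repeated runs are byte-identical.
* Empty inputs flow through: empty tables, empty KB, empty network and
  "no candidates" are ordinary values, not errors. Errors are reserved for
  *inconsistent* inputs (contradictory directions, dangling KB references,
  duplicate phenotype groups, constant correlation series).
* Reachability is breadth-first per (pathway, gene), giving shortest-path
  hop counts for the relation catalogue; results are invariant to edge-file
  order.
* The phenotype correlation requires ≥ 3 time points per dose; doses below
  that are skipped with a warning rather than failing the whole fit.

## Problem sizes in the test suite

The suite runs the worked-example fixture end-to-end (6 groups, 12 pathways,
~50 differential calls), property checks on ~200 random reaction graphs of
up to 30 nodes against a path-enumeration oracle, component decomposition on
random tripartite networks up to ~100 nodes against union-find, pair
screens up to 50 entities against an exhaustive double loop, and 20-seed
noise-free recovery runs — a few seconds in total, chosen to make the
equivalence arguments convincing while keeping the suite quick.

## Known limitations

* Name-based metabolite matching; no compound-ID resolution.
* One-to-one gene–protein mapping; isoforms out of scope.
* Co-membership joint mapping; no enrichment statistics or topology-impact
  scores.
* The reachability semantics ignore stoichiometry and flux; an annotated
  edge counts regardless of carbon fate.
* Correlations on three points are descriptive screening aids, not
  inference.
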