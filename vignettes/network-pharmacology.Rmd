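---
title: "Network pharmacology of a multi-component medicine: methods and design notes"
author: "netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology of a multi-component medicine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A complex medicine — here the essential oil of *Osmanthus fragrans* var.
*thunbergii*, but the machinery is generic — contains dozens of chemical
constituents, each of which may bind many protein targets, which in turn
participate in many biological pathways. Which constituents carry the
activity, and which proteins relay it, is not visible from the chemistry
alone. Network pharmacology answers this with graph models: ingredients,
targets and pathways become nodes; experimental or predicted
relationships become edges; and graph statistics rank the players.

`netpharm` implements that analysis as a reusable, tested pipeline:

1. **Screening.** Drug-likeness by Lipinski's rule of five, a minimum
   compound-support filter on targets, and removal of targetless
   ingredients.
2. **Enrichment.** Hypergeometric over-representation of pathways in the
   screened target set.
3. **Network construction.** The ingredient–target–pathway tripartite
   network, the core subnetwork around the key pathway, and the
   pathway-based protein association projection.
4. **Statistics.** Degree distribution and power-law fit, average path
   length `L`, diameter `D`, clustering coefficient `C`, and degree /
   betweenness / closeness centrality, plus hub ranking, centrality
   outlier flagging and a small-world comparison.

## Screening rules and their boundaries

The drug-likeness filter keeps a compound iff

- molecular weight `MW < 500` g/mol (strict), and
- H-bond donors `HBD <= 5`, H-bond acceptors `HBA <= 10`, and
  `MlogP <= 5` (all inclusive).

The mixed strict/inclusive boundaries mirror the printed operators of
the rule set as used in this field ("rule of five" names the historical
heuristic; four numeric criteria are applied). A compound at exactly
`MW = 500` is rejected; one at exactly `HBD = 5` is kept. Properties are
inputs (from PubChem/TCMSP-like sources), never computed from structure.

The target-support filter keeps a target iff it interacts with at least
`min_support = 5` distinct compounds; a target with 4 is removed. One
subtlety: public interaction databases apply this filter across *all*
compounds they index, not only the ingredients of one medicine. An
interaction table restricted to a single oil therefore cannot, in
general, re-satisfy the threshold — 191 targets × 5 compounds would
already need 955 interaction rows where the reference tripartite network
has 879 edges in total. The packaged paper-shaped dataset consequently
ships interactions *already support-filtered at source*, and pipeline
runs on it use `min_support = 1`. For raw interaction harvests the
default of 5 applies. The filter order (drug-likeness → target support →
targetless removal) follows the narrative order of the source protocol
and is configurable.

## Enrichment model

The test is the one-sided hypergeometric upper tail
`P(X >= k)` for `X ~ Hypergeometric(N_bg, K, n)`, with `K` the pathway
size inside the background, `n` the query size and `k` the overlap —
the standard over-representation statistic for pathway annotation. The
sum is accumulated in log space (`lchoose` + log-sum-exp), so tails
near machine minimum remain accurate; the suite checks agreement with
`stats::phyper` to 1e-12 relative error.

Two interpretation choices were genuinely open:

- **Test choice.** The source protocol names a *P*-value threshold
  (0.01) but no test; the hypergeometric upper tail is what KEGG-style
  annotation tools use, so that is what is implemented.
- **Background.** The universe is never stated. Default: the union of
  all pathway members and the query, overridable (`background =`); the
  paper-shaped dataset carries a genome-scale universe of 2000 proteins.
  Significance is called on the raw p-value by default, matching the
  apparent usage; Benjamini–Hochberg adjustment is available by flag and
  always reported alongside.

Because annotated-versus-significant pathway counts can be conflated in
narrative reports, the pipeline reports both (`n_pathways_annotated`,
`n_pathways_significant`).

## Network construction

All graphs are simple, undirected and unweighted — the statistics below
assume this. Shared-pathway counts survive only as an edge annotation on
the projection.

- **Tripartite network:** nodes are ingredients, targets, pathways;
  edges are interaction pairs and target–pathway memberships. Edges
  between two ingredients, two pathways, or an ingredient and a pathway
  are structurally impossible (the constructor refuses them, and refuses
  ids used in two roles).
- **Core subnetwork:** the "most important pathway" is operationalized
  as the pathway node of maximal degree (ties broken by ascending id),
  overridable by name. The subnetwork keeps that pathway, its adjacent
  targets `T`, the ingredients adjacent to at least one member of `T`,
  and only the pathway–`T` and ingredient–`T` edges. Whether ingredients
  should enter via any parent edge or only via `T` is not uniquely
  determined by the published counts; the `T`-only rule is used and
  reproduces them.
- **Projection:** two proteins are joined iff they share at least one
  pathway, computed as the Gram matrix of the pathway incidence matrix;
  proteins sharing no pathway with anybody are dropped ("isolated nodes
  excluded").

## Statistics

For node `i` with degree `k_i` and `e_i` edges among its neighbours:

- mean degree `⟨k⟩ = Σ k_i / N = 2E/N` (an exact identity, tested as
  such);
- clustering `C_i = 2 e_i / (k_i (k_i − 1))` for `k_i ≥ 2`. The formula
  is undefined below degree 2; `C_i := 0` there so the mean over all
  nodes is total (the `k ≥ 2`-restricted mean is reported alongside);
- `L` = mean breadth-first distance over connected unordered pairs, `D`
  its maximum; on disconnected graphs both are computed over reachable
  pairs and a flag records the disconnection;
- degree centrality `Cd = k_i / (N − 1)`;
- betweenness `Cb(i) = Σ_{j<k} g_jk(i)/g_jk` via Brandes' single-source
  accumulation (`O(N·E)`), with the brute-force geodesic-enumeration
  oracle existing purely in the test suite. Published top-ten tables in
  this field report values ≤ 0.2, implying a normalized variant, so both
  raw and `/((N−1)(N−2)/2)`-normalized scores are emitted;
- closeness `Cc(i) = (N − 1)/Σ_j d_ij`, evaluated per connected
  component (component size replacing `N`), 0 for singletons;
- power-law fit: ordinary least squares on `(log10 k, log10 P(k))` over
  nonzero entries, `γ = −slope`, with `r²`. This matches the qualitative
  scale-free claim the analysis makes; maximum-likelihood tail fitting
  (Clauset-style) is deliberately out of scope;
- small-world comparison: baselines are Erdős–Rényi `G(N, E)` graphs
  with matched node and edge counts (default 100 replicates, seeded;
  largest component used when a replicate is disconnected);
  `σ = (C/C_rand)/(L/L_rand) > 1` indicates small-world structure. The
  source analysis asserts small-worldness without a baseline; the
  explicit ensemble makes the claim testable;
- centrality outliers: a numeric stand-in for reading outliers off a
  3-D centrality scatter — a node is flagged when its robust z-score
  `(x − median)/MAD` exceeds 2 on any of `Cd`, `Cb`, `Cc`; if all three
  MADs vanish the top rank-sum node is flagged with a warning;
- rankings sort descending by the metric with ties broken by ascending
  node id, so results are identical across runs and platforms.

Serialization rounds global statistics to 2 decimals and centralities to
3 (round-half-even), matching the reporting precision of published
tables; all internal computation keeps full precision.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical shape* the analysis assumes:

- heavy-tailed ingredient connectivity with a few hubs
  (`hub_target_range`, default 90–110 targets, versus 1–15 for the
  rest);
- hub proteins recurring across many pathway sets;
- one dominant pathway covering `dominant_pathway_coverage` (default
  0.26) of the targets;
- a planted drug-like fraction (default 79/91).

`graph_from_degree_table()` rebuilds a concrete graph from a printed
degree-frequency table: the expanded sequence is checked for
graphicality (Erdős–Gallai, via `igraph::is_graphical`), stubs are
paired uniformly, and self-loops/parallel edges are repaired with
degree-preserving double-edge swaps; a stalled repair pass triggers a
re-seeded retry. The realized degree sequence always equals the request
exactly.

`paper_shaped_dataset()` is the deterministic counterpart: it
reconstructs, by construction rather than sampling, a dataset whose
funnel (91 → 79 → 44 compounds), network sizes (305 nodes/879 edges
tripartite; 59 nodes/150 edges core with composition 8 + 50 + 1) and hub
degrees (106, 96; core 47, 46) equal the published values. All
randomness elsewhere flows through one explicitly seeded private RNG
stream per dataset; the global RNG state is never touched.

What the synthetic data does **not** emulate: real chemistry
(physicochemical properties are sampled numbers, not descriptors), real
annotation bias (KEGG pathway sizes are far more skewed), and the
community structure of real protein networks. A consequence worth
stating: a configuration-model rebuild of a printed degree table
preserves every degree-based quantity (`⟨k⟩`, `P(k)`, `Cd`) exactly, but
*not* path lengths or clustering — the real association network is
modular, so its published `L` (2.59) exceeds the rebuild's (~1.9).
Passing tests on synthetic data therefore validate the algorithms and
the degree-level arithmetic, not claims about unpublished edge lists.

## Numerical choices and degenerate inputs

- The planted-exponent recovery experiment draws 2000 degrees from an
  exact `k^(−2.5)` law supported on `k = 1..30`. The cutoff keeps the
  expected count of the largest degree near 1; far longer supports fill
  the tail with single-count bins, which biases any least-squares
  histogram slope downward (the known weakness of log-log regression
  that ML tail fitting avoids — but the log-log fit is the estimator
  this analysis actually uses, so it is what is validated).
- Empty graphs yield all-null reports with a warning; single-node
  graphs have no path statistics; pathways emptied by background or
  target restriction are skipped with a message.
- Duplicate membership entries in GMT files are deduplicated silently at
  collection construction.
- Ties: everywhere, ascending node id.

## Problem sizes

The test suite and the acceptance script run the pipeline at the
reference scale (305-node tripartite network, 142-node rebuilt
association network), the oracle-equivalence suites on 200 random graphs
of ≤ 30 nodes plus 50 membership collections of ≤ 200 proteins, the
exponent-recovery experiment at N = 2000, and the enrichment calibration
on 1000 parameter draws and 1000 permutations — sizes at which the
exhaustive oracles remain exact and the whole suite completes in about a
minute.

## Known limitations

- Pajek support covers the undirected `*Vertices`/`*Edges` dialect with
  a `.clu` role partition; `*Arcs`, `*Matrix` and multi-relational files
  are out of scope, as are GraphML/SBML.
- No eigenvector/PageRank/Katz centrality, no weighted shortest paths.
- The enrichment background default (union of pathway members and
  query) is conservative when memberships cover only hit targets —
  supply a genome-scale universe for realistic p-values.
- Whether published betweenness columns divide by `(N−1)(N−2)/2` or
  `(N−1)(N−2)` cannot be settled without the original edge lists; both
  normalizations are emitted.
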