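---
title: "Methods: multi-omic interactome assembly, virtual knockout and map comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic interactome assembly, virtual knockout and map comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netperturb)
```

netperturb implements a network-medicine workflow for diseases described by
molecular evidence of heterogeneous biochemical origin — the motivating case
is rheumatoid arthritis (RA), where genomic, epigenomic, transcriptomic,
post-transcriptomic, proteomic and host–microbiome-interface screens each
contribute molecule lists. The workflow has four analytical stages:

1. **Catalog assembly.** Overlapping molecule subsets from the different
   data sources are unioned into a node catalog; each molecule keeps all its
   subset memberships, and subsets map to one of 8 fixed biochemical
   *districts* (Genomic, Epigenomic, Transcriptomic, Post-transcriptomic,
   Proteomic, Microbiome, Inflammation, Others).
2. **Interactome construction and topology.** The catalog is intersected
   with a protein–protein interaction edge table; only edges with both
   endpoints catalogued are kept, and all topology (degree, betweenness,
   stress) is computed on the main connected component.
3. **Pharmacological simulation.** A drug's protein targets are deleted
   from the network; per-node changes in betweenness and stress centrality
   are tested against a permutation null of random equal-size deletions,
   with Benjamini–Hochberg control of the false discovery rate.
4. **Map comparison.** Node importance (degree percent-rank) is compared
   between a directed single-omic map and the undirected multi-omic map,
   classifying shared nodes as *climbers*, *losers* or *accomplished*.

A synthetic-data module generates all inputs with the statistical structure
these stages assume, so the entire pipeline runs and is tested without any
database access.

## Centrality measures

For a connected unweighted undirected graph, with $\sigma_{st}$ the number
of shortest $s$–$t$ paths and $\sigma_{st}(v)$ those passing through an
interior node $v$:

$$BC(v) = \sum_{s<t,\; s\neq v\neq t} \frac{\sigma_{st}(v)}{\sigma_{st}},
\qquad
S(v) = \sum_{s<t,\; s\neq v\neq t} \sigma_{st}(v).$$

Betweenness measures the control a node exerts over communication between
other nodes; stress is its un-normalized companion, counting paths rather
than fractions, so $S(v)\ge BC(v)$ always. Divergence between the two after
a perturbation is informative: a node whose betweenness rises while its
stress falls has become a bottleneck for *more pairs* but *fewer paths* — a
network that has "shrunk" onto it.

Numerical choices:

* Betweenness is reported **unnormalized** (raw pair-fraction sums). Within
  one network, normalization by $(n-1)(n-2)/2$ is a constant factor and
  does not change ranks; `betweenness_centrality(..., normalized = TRUE)`
  is available for cross-network display.
* Endpoints are excluded from their own path counts (the standard
  convention).
* Betweenness is delegated to igraph's Brandes implementation; stress has
  no R implementation in our dependency set and is authored here as a
  Brandes-style BFS accumulation in C++ (`src/stress.cpp`). Both are
  verified in the test suite against a brute-force oracle that explicitly
  enumerates every shortest path on graphs of up to 30 nodes.
* Path counts are accumulated in doubles: on hub-dense graphs
  $\sigma_{st}$ overflows 32-bit integers long before memory is a concern.
* Ranks are dense (1 = largest, ties share the smallest applicable rank).
  Percent rank uses the spreadsheet convention
  $(\#\{x_j < x_i\})/(n-1)$: minimum 0, maximum 1, ties share values. This
  is one of several tie conventions in circulation; it is applied uniformly
  to both maps in the comparison, so classification is unaffected by the
  choice except exactly at the tolerance boundary.

## Virtual knockout and the permutation null

`knockout()` removes the target set from the baseline main component and
recomputes both centralities on the **largest surviving component**;
surviving nodes cut off from it receive centrality 0 and a `disconnected`
flag. The alternative of recomputing within every fragment is available
(`fragment_mode = "per_fragment"`) because the two procedures genuinely
differ when removal fragments the graph, and their agreement fraction —
`concordance()` — is itself a useful robustness diagnostic for a removal
experiment. Agreement is defined as equality of the per-node
centrality-change values within relative tolerance $10^{-6}$, on the nodes
common to the two results.

The null model deletes `null_k` nodes (defaulting to the number of targets
present in the baseline) uniformly at random, `n_null` times, and records
each surviving node's absolute betweenness change. The per-node empirical
p-value uses the add-one estimator

$$p(v) = \frac{1 + \#\{b : |\Delta_b(v)| \ge |\Delta_{\mathrm{obs}}(v)|\}}
{B_v + 1},$$

where $B_v$ counts the draws in which $v$ itself survived — a node can be
deleted in a draw, and those draws contribute no sample for it, so the
denominator is tracked per node rather than discarding whole draws. The
estimator never returns 0 and is in $(0,1]$ by construction. The default
statistic is two-sided ($|\Delta BC|$), since "significantly altered" does
not presuppose a direction; a signed mode is behind the `directional` flag.
Benjamini–Hochberg is applied across all tested nodes (nodes with
$B_v = 0$ are excluded from the family), consistent with the BH correction
used for over-representation analysis elsewhere in the pipeline.

Under the null — targets drawn uniformly — these p-values are close to
uniform; the acceptance suite checks a Kolmogorov–Smirnov distance
$\le 0.1$ pooled over 20 repetitions at `n_null = 500` on a 200-node graph,
and that BH at $\alpha = 0.05$ declares essentially nothing. A consequence
worth stating: with a few thousand tested nodes, the smallest achievable
BH-adjusted p-value at `n_null` draws is about `n_tests`/(`n_null`+1)
divided by the number of nodes tied at the minimum, so detecting a handful
of significant nodes requires either a strongly non-null target set or a
large ensemble. When uniformly drawn synthetic targets are knocked out, an
empty significant set is the *calibrated* outcome, not a failure.

## Expression filter and over-representation

`collapse_probes()` retains, per gene, the probe with the highest standard
deviation across **all** samples (both groups pooled; sample SD with
$n-1$ denominator); ties break to the lexicographically smallest probe ID
so results are reproducible. `fold_change_filter()` assumes log2-scale
input (e.g. rma-normalized arrays) and interprets a fold-change threshold
of 2 as $|\overline{\log_2 b} - \overline{\log_2 a}| \ge 1$, inclusive.
The linear-scale alternative reading (ratio of anti-logged means) is not
implemented: on rma output the log-scale reading is the standard one, and
the threshold's inclusivity matters only on a measure-zero boundary.

`hypergeometric_ora()` computes the inclusive upper tail
$P(X \ge k)$ with population $N$ = universe, successes $K$ = pathway
members inside the universe, draws $n$ = gene-list size — the standard
over-representation convention — followed by BH across all tested
pathways. The test suite checks it against direct combinatorial
enumeration ($\sum_k \binom{K}{k}\binom{N-K}{n-k}/\binom{N}{n}$) for
universes up to 50.

## Directed-to-undirected comparison

A directed regulatory map represents some proteins twice — the protein and
a modified instance (e.g. a kinase and its phosphorylated form). For
degree comparison with an undirected map these pairs are *complex nodes*:
`merged_directed_degree()` collapses each group and counts **distinct
external endpoints** of arcs incident to any member, internal arcs
excluded; ungrouped nodes count distinct neighbours ignoring direction
(reciprocal arcs collapse to one neighbour). The naive "sum in- and
out-degrees, subtract internal edges once" recipe double-counts: an
internal arc appears in one member's out-degree *and* the other member's
in-degree, so it must leave the sum twice. The distinct-endpoint
definition does this implicitly and is the only variant consistent with
the simple-graph degree used on the undirected side; the literal
single-subtraction variant is kept behind
`internal = "literal_subtraction"` for comparison, and the two genuinely
differ on maps with reciprocal or internal arcs.

`classify_transitions()` percent-ranks degree within each map (each over
its own full node set — the two maps differ in size, which is the reason
for using percent-ranks at all), then classifies nodes present in both
maps by $\Delta = \mathrm{prank}_{EI} - \mathrm{prank}_{TR}$: climber if
$\Delta > t$, loser if $\Delta < -t$, accomplished otherwise, with the
band inclusive at $\pm t$. The default tolerance $t = 0.10$ treats rank
shifts within ten percentage points as preservation — a zero tolerance
would count only exact rank matches, which is topologically clean but
biologically uninformative.

## The synthetic study

The generator defaults describe one fixed synthetic study whose shape
follows the motivating RA analysis:

| parameter | default | what it emulates |
|---|---|---|
| `n_nodes`, `n_edges` | 3466, 24364 | the multi-omic interactome's main cluster |
| `degree_model` | preferential attachment | heavy-tailed PPI degree distribution |
| subset sizes | 19 source sizes scaled | the 13 data sources (with split sub-sources) |
| `subset_overlap` | 0.51 | source sizes summing to ~2× their union |
| `extra_molecule_fraction` | 0.25 | catalogued molecules with no interaction record |
| `directed_map_size` | 302 | the transcriptional-only directed map |
| `n_complex_nodes` | 10 | protein/phospho-protein complex nodes |
| `target_set_size` | 20 | the methotrexate target list |
| `expr_groups` | 2, 2 | healthy vs pre-treatment microarray samples |
| `expr_n_probes`, `planted_fraction` | 1000, 0.1 | a small array with a plantable DE signal |
| `planted_log2fc`, `noise_sd` | 1.2, 0.1 | recoverable twofold changes under noise |
| `planted_down_fraction` | 0.68 | the down/total ratio of the emulated comparison |

Preferential attachment is used because protein-interaction maps are
heavy-tailed; no generative model is claimed for the real network, and the
`configuration` option (a power-law-fitness configuration-style model with
identical node and edge counts, which a stub-matching construction cannot
guarantee while staying simple) exists precisely so conclusions can be
checked against an alternative null. Complex nodes are generated as pairs,
matching the protein/modified-instance structure; larger groups are
supported by the data structures but not generated by default. Expression
is generated directly on the log2 scale — array normalization is upstream
of this package's scope.

What the generator does **not** emulate: biological pathway semantics,
correlated expression between genes, degree–annotation correlations (a
real drug's targets are biased toward particular network positions;
synthetic targets are uniform draws), and identifier-mapping noise between
gene and protein namespaces. Tests passing on synthetic data therefore
demonstrate the correctness and calibration of the computations, not the
biological conclusions one would draw on curated data.

All generators are pure functions of (config, seed); each consumes its own
RNG stream derived from the master seed, and the surrounding R session's
RNG state is saved and restored around every draw.

## Problem sizes in the test and acceptance runs

The test suite exercises exact oracles on graphs up to 30 nodes (where
all-shortest-path enumeration is feasible), permutation-calibration on a
200-node graph with 500-draw ensembles over 20 repetitions, and one
full-scale pipeline run (3466 nodes / 24364 edges) with a 100-draw null
ensemble, executed twice to verify byte-identical reproducibility. The
acceptance script repeats the full-scale run and reports its headline
quantities; the 100-draw ensemble is a scaled stand-in for the 1000-draw
design, chosen so a complete run stays in the minutes range on one core —
conclusions that depend on the ensemble size (see the note on minimum
achievable adjusted p-values above) are stated with that scaling in mind.

## Known limitations

* Exact betweenness/stress recomputation per null draw is $O(nm)$ per
  draw; ensembles beyond ~10³ draws on graphs beyond ~10⁴ nodes call for
  approximation or parallelism, both out of scope.
* The concordance statistic compares the two removal procedures
  implemented here; it is a robustness diagnostic, not a re-creation of
  any specific external tool's output.
* Weighted or directed betweenness, closeness/eigenvector centrality, and
  identifier conversion between naming schemes are not implemented.
* The DE filter is a pure fold-change rule (by design, matching the
  emulated analysis); it ignores variance and is not a substitute for a
  moderated test when replicates allow one.
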