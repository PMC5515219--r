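---
title: "Methods: KO-level community metabolic networks and keystone-gene selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KO-level community metabolic networks and keystone-gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(konet)
```

## The model

konet treats a microbial community as one meta-organism whose enzymatic
repertoire is summarised at the KEGG-orthology (KO) level. Three ideas are
combined:

**Relative gene expression.** For each KO, the metagenomic layer yields a
gene-copy abundance (KOGA) and the metatranscriptomic layer a transcript
abundance (KOTA), each computed as the sum over member genes of
`count / effective_length`. Effective length — the number of positions a
read can start at, `max(1, gene_length − read_length + 1)` in the synthetic
generator — removes the bias whereby longer genes accrue proportionally
more reads at equal copy number. The ratio `KOTA / KOGA` is the relative
gene expression: a function carried by a rare population but transcribed
intensely scores high, which is exactly the signature one expects of
keystone activity. The ratio assumes the two layers are comparable, which
is why `subsample_counts()` can first bring both libraries to an identical
depth by a multivariate hypergeometric draw (sampling reads without
replacement from the mapped-count table). We deliberately apply no further
rescaling after subsampling: equal depths make raw ratios comparable, and
any common factor cancels in the ranking that drives selection.

**A connectivity-centred metabolic network.** Each KO carries a pair-set
of (substrate, product) metabolites. Nodes are KOs (or groups of KOs after
collapsing); an undirected edge labelled *m* joins two nodes whose
pair-sets both touch *m*. This "shared metabolite" rule is the default
because it reflects the connectivity-centred reading of community
metabolism: two enzymes handling the same compound are potential
metabolic neighbours regardless of direction. A stricter `complementary`
mode (the metabolite must be a product of one node and a substrate of the
other) is available; its edge set is provably a subset of the default's.
Parallel edges — one per distinct shared metabolite — are retained in the
data model because the total edge count `Σe` in the load score counts
metabolite links, not just adjacencies. Self-loops are never created.
KOs expressed in a sample but lacking pair annotations are excluded (with
a warning): only KOs with metabolic functions can join the network.

**Load points and choke points.** The load score of node *n* is

$$\mathrm{load}(n) = \frac{\sum_{s \ne n \ne t} \sigma_{st}(n)/\sigma_{st}}{k_n \, \Sigma e},$$

betweenness centrality over unordered node pairs (endpoints excluded,
exact Brandes-style σ counting, computed per connected component on the
simple underlying graph) divided by node degree times total edge count.
Dividing by degree distinguishes genuinely route-critical nodes from mere
hubs; dividing by `Σe` makes scores comparable across networks of
different size. Choke points are nodes whose pair-set contains a
metabolite no other node touches — sole consumers or producers. Selection
of "genes encoding key functionalities" intersects the top decile of load
scores with the top decile of relative expression.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `load_quantile`, `expr_quantile` | 0.10 | fraction of ranked entities | the dual top-10 % criterion; smaller is stricter |
| `tie_policy` | `include_ties` | — | with ties at the cut, keep all (reproducible without arbitrary ordering); `strict` takes exactly `ceiling(q·N)` with id-ordered tie-breaks |
| `group_expr` | `max` | — | a collapsed group is as expressed as its most expressed member; `sum`/`mean` available |
| `edge_count_convention` | `parallel` | — | `Σe` and `k_n` count one edge per shared metabolite; `simple` counts adjacencies once, for sensitivity analysis |
| `mode` | `shared_metabolite` | — | see above |
| mt-only `policy` | `flag` | — | a KO with transcripts but zero detected gene copies has an undefined ratio; flagging avoids fabricating infinite expression (a `pseudocount` alternative substitutes the smallest positive KOGA) |
| `normalized` betweenness | `FALSE` | — | dividing by `(N−1)(N−2)/2` rescales all scores equally; ranking within a fixed network is unchanged, so the raw definition is kept |
| `exclude_metabolites` | none | metabolite ids | optional currency-metabolite filter; by default the pair-map annotations are trusted to limit spurious connectivity |

## Numerical and degenerate-input choices

- **Quantile thresholds** are order statistics: the threshold is the
  `ceiling(q·N)`-th largest value, so with distinct scores exactly
  `ceiling(q·N)` entities pass; ties at the threshold are included by
  default. A node with zero relative expression never passes the
  expression criterion, whatever the threshold — without this rule a
  degenerate distribution whose 90th percentile is 0 would select
  unexpressed nodes.
- **Isolated nodes** (degree 0) get load score 0 and an `isolated` flag
  rather than a division error.
- **MT-only KOs** are excluded from percentile ranking under the default
  policy (their `rel_expr` is `NA`).
- **Fold changes at zero:** in seasonal betweenness comparisons, pairs
  with zero betweenness in either season are excluded from the median fold
  change (fold change is undefined at 0) but counted and reported; the
  Wilcoxon signed-rank test uses all shared pairs. Pathways with fewer
  than two shared KOs are skipped with a warning. When the two seasons are
  identical the p-value is defined as 1 (no signed ranks exist).
- **Pathway enrichment** uses the one-sided Fisher exact test
  (hypergeometric) with Benjamini–Hochberg adjustment across tested
  pathways; a pathway with no selected members has p = 1 by construction.
- **Read-weight conservation** is exact up to floating point; tests assert
  it at 1e-9. Betweenness agreement with an independent path-enumeration
  oracle is likewise asserted at 1e-9.
- **Multi-KO genes** contribute their full abundance to every assigned KO
  by default (KO abundance is defined as a sum over all genes belonging to
  that KO); `multi_ko = "split"` divides the abundance evenly instead.

## The occurrence-weighted load score

The variant replaces hop counts by weighted shortest paths in which an
edge labelled *m* has length `occurrence(m)`, the number of nodes whose
pair-set touches *m*. Routes through ubiquitous (currency-like)
metabolites are thereby penalised and geodesics are pushed through
pathway-specific compounds, which is the stated purpose of weighting by
metabolite occurrence. Between two nodes linked by several metabolites the
cheapest (rarest) label is used. When every metabolite has the same
occurrence the weighted ranking coincides exactly with the unweighted one.
This variant is our own reconstruction of an under-specified idea; it is
reported in the topology table but deliberately excluded from default
keystone selection.

## What the synthetic generator emulates — and what it does not

`simulate_community()` produces the full input bundle with known ground
truth. Its default configuration *is* the study condition used throughout
validation: 4 pathway modules of 14 KOs (each module a clique around a hub
metabolite, every member also making one private product), 1 redundant
subunit KO per module (identical pair-set, to exercise collapsing), and
4 bridge KOs joining adjacent modules in a ring by linking two private
products. Bridges are cut-vertex candidates with degree 2, hence
ground-truth load points. Genes per KO are drawn uniformly from 1–3 with
lengths 300–1500 nt (read length 100 nt, effective length
`max(1, length − 99)`). MG counts are negative binomial (dispersion 0.3,
a typical overdispersion for shotgun counts) with means proportional to
effective length times a log-normal (sdlog 0.5) per-KO community
abundance, scaled to an expected depth of 2×10⁵; MT counts use the same
baseline times an expression multiplier — 10 for planted bridges, 1
otherwise. Because the same per-KO abundance enters both layers, expected
relative expression is flat except at planted keystones, and when the
boost is set to 1 no KO-level expression signal exists at all.

The generator emulates the *count structure* of KO-annotated multi-omic
layers, not real sequencing: there are no sequence errors, no mapping
ambiguity beyond what `weight_multimapped()` is separately tested on, no
compositional coupling between taxa, no pair-set incompleteness, and its
module/bridge topology is far more regular than a real reconstruction.
Passing the recovery checks therefore demonstrates that the statistical
and topological machinery identifies planted signals under controlled
noise — not that real communities will yield equally clean separations.

## Validation sizes

The test-suite problem sizes are chosen to make exhaustive oracles
feasible while exercising non-trivial structure: ~100 random graphs of
8–30 nodes (plus 3-block modular graphs) against a pure-R BFS
path-enumeration oracle; 100 random pair maps of up to 50 KOs for the
collapsing partition oracle; 1,000 random read-assignment tables for
conservation; exhaustive signed-rank enumeration up to n = 12; and 25
independent synthetic communities for keystone recovery. The acceptance
script repeats the recovery measurement over 25 communities at the default
depths.

## Known limitations

- Pair-set annotations are taken as given; no stoichiometry, mass balance,
  compartments or flux modelling.
- The undirected shared-metabolite rule can connect enzymes that never
  exchange matter in vivo; the `complementary` mode and the
  currency-metabolite exclusion list are partial mitigations.
- Protein abundances are ingested and reported but do not enter selection.
- The top-decile expression cut is computed over network-included nodes;
  communities where most annotated KOs lack pair annotations would rank
  expression over a restricted universe (a switchable design choice).
- Betweenness on very large networks is O(|V|·|E|); the igraph
  implementation handles networks of a few thousand nodes comfortably,
  which covers community-scale KO networks.
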