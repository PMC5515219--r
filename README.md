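# konet

Community-wide metabolic networks and keystone-gene selection from
multi-omic KO abundance data.

## What it does

Microbial communities — such as the lipid-accumulating biomass floating on
wastewater treatment tanks — carry out their chemistry collectively.
Sequencing the community metagenome (MG) tells you which gene functions are
*present*; the metatranscriptome (MT) tells you which are *expressed*. konet
integrates both layers at the level of KEGG orthologous groups (KOs) to find
**genes encoding key community functionalities**: enzymes that sit at
topologically critical positions of the community's metabolic network *and*
are disproportionately highly expressed. Such genes are candidate markers of
keystone populations — low-abundance members with outsized influence on the
community phenotype.

The workflow:

1. **Quantify** — per-gene read counts from each omic layer are optionally
   subsampled to a common depth (multivariate hypergeometric, so libraries
   are comparable), cross-mapping reads are fractionally weighted
   (`1/k` to each of the `k` genes a read maps to), counts are normalised by
   effective gene length, and length-normalised abundances are summed per KO.
   This yields the KO gene-copy abundance (KOGA) from the MG layer, the KO
   transcript abundance (KOTA) from the MT layer, and **relative gene
   expression** `KOTA / KOGA` — expression normalised to underlying gene
   copy number, which highlights active low-abundance functions. Per-KO
   protein abundances (normalised spectral index) can be attached as a third,
   ingested layer.
2. **Reconstruct** — each KO carries a pair-set of (substrate, product)
   metabolites (reactant-pair style annotations). Enzymes (KOs) become
   nodes; an undirected edge labelled with metabolite *m* connects two nodes
   whose pair-sets both touch *m*. One edge is kept per shared metabolite,
   so parallel edges are part of the model. Networks are made
   season-specific by keeping only KOs with mapped transcripts in a sample,
   and non-redundant by merging KOs with identical pair-sets (typically
   subunits of one enzyme) into a single node.
3. **Score topology** — for every node *n* the package computes degree
   `k_n`, betweenness centrality `b_n = Σ_{s≠n≠t} σ_st(n)/σ_st`, and the
   **load score**

   ```
   load(n) = b_n / (k_n · Σe)
   ```

   where `Σe` is the total number of edges. High-load nodes ("load points")
   funnel many metabolite conversion routes relative to their connectivity.
   Choke points — sole consumers/producers of some metabolite — are flagged,
   and an occurrence-weighted load-score variant down-weights ubiquitous
   currency metabolites.
4. **Select** — key functionalities are nodes in the top 10 % of the load
   score distribution *and* the top 10 % of relative expression (both
   quantiles configurable). Companion statistics: one-sided Fisher pathway
   enrichment with Benjamini–Hochberg FDR, and paired Wilcoxon comparisons
   of per-pathway betweenness between two seasonal networks.

A synthetic multi-omics generator with planted ground truth (bridge KOs
connecting pathway modules, given an MT expression boost) makes the entire
pipeline testable end to end without any external data.

## Worked example

```r
library(konet)
library(dplyr)

bundle  <- simulate_community(synth_config(), seed = 7)
profile <- ko_profile(bundle$mg_counts, bundle$mt_counts, bundle$catalogue)
expressed <- season_subset(bundle$pair_map,
                           select(profile, ko_id, kota = kota))
net <- collapse_redundant(build_network(bundle$pair_map, expressed))
net
#> <metabolic_network> 60 nodes, 372 metabolite edges (mode: shared_metabolite, non-redundant)
glance(net)
#> # A tibble: 1 × 7
#>   n_nodes n_edges_parallel n_edges_simple n_components avg_shortest_path ...
#> 1      60              372            372            1              3.85

topo   <- topology_table(net)
report <- select_key_functionalities(topo, profile)
report
#> <keystone_report> 4 of 60 nodes selected
#>   load score >= 0.08074 (top 10%), relative expression >= 2.519 (top 10%)
#> # A tibble: 4 × 7
#>   node_id members   degree betweenness load_score choke_point rel_expr
#> 1 K00061  <chr [1]>      2        420.      0.565 FALSE           3.26
#> 2 K00062  <chr [1]>      2        420.      0.565 FALSE           8.05
#> 3 K00063  <chr [1]>      2        420.      0.565 FALSE           4.48
#> 4 K00064  <chr [1]>      2        420.      0.565 FALSE           5.39

keystone_recovery(report, bundle$truth)
#> # A tibble: 1 × 5
#>   n_planted n_selected_kos n_recovered sensitivity false_positive_rate
#> 1         4              4           4           1                   0
```

Reading the output: the synthetic community has four pathway modules joined
in a ring by four bridge enzymes. The collapsed network has 60 nodes and an
average shortest path length of 3.85 (small-world range). The four selected
nodes are exactly the planted bridges: their betweenness (420) equals that
of the module hubs they connect, but at degree 2 instead of 14 their load
score is seven-fold higher, and their 10× transcript boost puts them in the
top expression decile — so sensitivity is 1 with no false positives.
`autoplot(report)` draws the load-score × expression scatter with the two
selection thresholds as dashed lines.

File-based inputs work the same way: `read_gene_catalogue()`,
`read_counts()`, `read_pair_map()`, `read_pathway_map()` read the TSV
contracts described in the function documentation, and `run_pipeline()`
(or `inst/cli/konet.R run --config pipeline.yaml`) orchestrates all stages,
writing every intermediate table, GraphML/SIF network exports, a keystone
report with a JSON threshold sidecar, and a provenance record with file
checksums.

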