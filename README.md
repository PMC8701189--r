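# mirmod

Network-based discovery of signaling-pathway modules co-regulated by a set
of microRNAs.

## The problem

A disease-associated set of miRNAs (for example, miRNAs dysregulated in
diseased heart muscle) rarely acts through a single target gene. Each
miRNA represses hundreds of targets; the targets interact; and several
miRNAs may press on the *same* region of the signaling network. `mirmod`
asks: **which pathways are jointly regulated by a given miRNA set in a
given tissue?** It is aimed at computational biologists who have a target
catalog (miRTarBase-like), a tissue expression table (Human Protein
Atlas-like), a scored protein–protein interaction network (STRING-like)
and a pathway collection in GMT format (Reactome-like), and who want a
reproducible, file-based reimplementation of the workflow — no web-service
calls.

## The method

For each query miRNA *m*:

1. **Expressed target network.** Keep targets with expression ≥ 1 nTPM in
   the chosen tissue; build the vertex-induced subgraph of the interaction
   network (edges with combined score ≥ 0.9) on those targets, and extract
   its largest connected component (LCC).
2. **Key genes.** On the intact LCC compute, for every node *v*,
   normalized degree `deg(v)/(n−1)` and pair-normalized betweenness
   `2·B(v)/((n−1)(n−2))`, and order nodes by the sum. Remove nodes in that
   order, recording the LCC cardinality `S(k)` after each removal. Stop at
   the knee of the decay curve (maximal vertical distance to the chord);
   the removed prefix is the key-gene set — the nodes whose loss
   disintegrates the network.
3. **Overrepresentation.** Test each pathway for enrichment of the key
   genes with the upper-tail hypergeometric probability
   `P(X ≥ k)` over the universe of pathway-annotated, tissue-expressed
   genes; control FDR with Benjamini–Hochberg (q < 0.05).
4. **Bigraph and greedy covering.** Connect miRNA *m* to every pathway its
   key genes enrich. On this bipartite graph, repeatedly select **all**
   pathways tied at the maximal number of covered miRNAs (a *module*),
   remove them and their miRNAs, and iterate (default twice). When no two
   miRNAs are linked through pathways, the same search runs on the
   miRNA–key-gene bigraph instead.
5. **Monte Carlo significance.** Compare the observed bigraph's
   pathway-degree distribution (default statistic: mean pathway degree)
   and the first module's miRNA coverage against the same pipeline run on
   random same-sized miRNA sets drawn from the whole catalog; report
   add-one-corrected empirical p-values.
6. **Consistency.** A node-ejection test removes growing random fractions
   (10%…90%) of non-key LCC nodes and re-extracts key genes, quantifying
   how stable the key-gene set is.

A synthetic-data generator emulates all four input files with controllable
planted co-regulation structure, so the entire workflow is testable
offline.

## Worked example

```r
library(mirmod)

# synthetic dataset: 40-miRNA catalog, 12 queried, a 3-pathway module
# planted into 8 of them
d <- generate_dataset(synth_config(k_planted = 8, seed = 11))
run <- run_pipeline(d$catalog, d$profile, d$ppi, d$collection, d$query)
run
```

```
miRNA-module run [1c40743b]: 12 miRNA(s), pathway bigraph, 1 module(s)
          mirna total expressed in_lcc key_genes expressed_pct in_lcc_pct key_genes_pct
 syn-miR-004-3p   140        82     73        12            59         52             9
 syn-miR-007-3p   178        97     84        40            54         47            22
 syn-miR-013-3p    80        43     42        25            54         53            31
 ...
 syn-miR-040-3p    75        41     41        25            55         55            33
Module (iteration 1): 3 node(s) covering 8 miRNA(s)
  nodes: SYN-PW-0003, SYN-PW-0033, SYN-PW-0043
  miRNAs: syn-miR-007-3p, syn-miR-013-3p, syn-miR-027-3p, syn-miR-028-3p, ...
```

The summary table is the per-miRNA audit: raw target count, how many are
tissue-expressed, how many sit in the LCC, and how many were extracted as
key genes (with percentages of the total, rounded half away from zero).
The first greedy module here recovers exactly the three planted pathways
and the eight planted miRNAs. Monte Carlo significance:

```r
degree_shift_test(run$bigraph, d$catalog, d$profile, d$ppi, d$collection,
                  pipeline_config(), size = 12, iterations = 1000, seed = 42)
#> Monte Carlo null ('mean_degree'): observed 8, 1000 iteration(s), empirical p = 0.000999
```

A command-line wrapper with `run`, `simulate`, `null` and `robustness`
commands lives at `inst/cli/mirmod.R` (YAML-configured; see its header).

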