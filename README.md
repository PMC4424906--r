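# tsnetalign

Tissue-specific protein-interaction networks and stochastic multiple
differential local alignment, for systems biologists who want to ask: *which
conserved protein complexes change expression the most between conditions --
say, a normal tissue and successive tumor grades?*

A tissue-specific PPI (TS-PPI) network is the subgraph of a global
interactome induced by the genes expressed in one tissue or tumor, so both
endpoints of every edge are expressed there.  `tsnetalign` covers the whole
pipeline:

* **Integration** -- merge interaction datasets (weighted or not) into a
  global gene-interaction network carrying, per edge, the average weight
  across reporting datasets and the *dataset coverage* (fraction of
  datasets reporting it); merge expression datasets (log2 transform,
  Bolstad quantile normalization, probe-to-gene averaging) into one
  positive expression score per (gene, condition).
* **TS-PPI construction** -- per-condition filtering by gene list,
  expression score, edge weight, coverage, and dataset selection.
* **Differential alignment** -- a Gibbs-sampled seed-and-extend search over
  N node-weighted networks for conserved connected subnetworks maximizing
  cross-network expression divergence.

Divergence of an aligned column G = {G1, ..., GN} (one gene per network) is

    LogFold(A, B)  = log2( max(Expr A, Expr B) / min(Expr A, Expr B) )
    MaxLogFold(G)  = max over pairs i < j of LogFold(Gi, Gj)

Extension admits only columns with MaxLogFold at or above a threshold
(default 0.6 log2 units), the refinement loop alternately extends and
deletes the least divergent column, and results are ranked by the Index of
Structural Conservation -- the fraction of aligned gene pairs whose
interaction is conserved in *all* networks among those present in at least
one -- then pruned for overlap.  The Gibbs sampler stops after
`k = max { k' : ((N-1)/N)^k' > alpha }` unchanged iterations.

## Worked example

Generate a synthetic four-network family (300 genes on a shared scale-free
backbone; a planted connected module of 8 genes with pairwise divergence
at least 2 against a background below 0.3) and align it:

```r
library(tsnetalign)
inst   <- generate_instance(synthetic_spec(seed = 1))
result <- align_networks(inst$networks,
                         params = alignment_parameters(seed = 2))
result[[1]]
#> Local alignment: size 8 over 4 networks, avg MaxLogFold 2.073, ISC 1
score_recovery(result, inst$truth)
#> $precision [1] 1   $recall [1] 1   $f1 [1] 1
head(result[[1]]$columns, 3)
#>      net1    net2    net3    net4
#> [1,] "G0198" "G0198" "G0198" "G0198"
#> [2,] "G0186" "G0186" "G0186" "G0186"
#> [3,] "G0139" "G0139" "G0139" "G0139"
```

The top alignment maps 8 genes across the four networks (label-identity
homology, so each row repeats one gene), every column's MaxLogFold is
about 2.0--2.1 (a four-fold or larger expression spread across
conditions), all 8 planted genes are recovered with nothing spurious
(F1 = 1), and every aligned interaction is conserved in all four networks
(ISC = 1).

The same pipeline runs from the shell -- see
`inst/cli/tsnetalign.R --help` for the `simulate`, `integrate`, `build`,
`align` and `evaluate` subcommands:

```sh
Rscript inst/cli/tsnetalign.R simulate --out sim --seed 11
Rscript inst/cli/tsnetalign.R align \
    --network net1=sim/net1.tsv --network net2=sim/net2.tsv \
    --network net3=sim/net3.tsv --network net4=sim/net4.tsv \
    --out alignments --seed 7
Rscript inst/cli/tsnetalign.R evaluate --alignments alignments \
    --truth sim/truth.tsv
```

Real data enter through plain tab-delimited files: interaction pair lists,
expression matrices (first row tissues, first column genes), TS-PPI network
records (`gene_a  gene_b  tissue  expr_a  expr_b  weight`), and optional
homology score files; see `?read_interaction_file`,
`?read_expression_matrix`, `?read_tsppi_network`, `?read_homology_file`.

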