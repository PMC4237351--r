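# netnoise

Network-based recovery of sub-threshold GWAS association signal.

## The problem

GWAS of polygenic disorders often end with no genome-wide-significant
hit: risk is spread across many variants of small effect, each invisible
to single-SNP testing. If the hidden risk genes share biology, their
protein products should cluster on a protein–protein interaction (PPI)
network while statistical noise scatters. `netnoise` implements that
test and the downstream prioritization as a reusable pipeline for
statistical geneticists and systems biologists:

1. **Gene scoring.** SNPs are assigned to genes within a symmetric
   window (default ±10 kb); each gene's best SNP p-value is corrected
   for gene size and SNP density by forward-stepwise regression on
   −log₁₀ *p* and an empirical-rank transform, giving corrected
   gene-wise p-values *p*ᶜᵒʳʳ ∈ (0, 1) that are an exact permutation of
   *i*/(*N*+1).
2. **Projection.** Genes with −log₁₀ *p*ᶜᵒʳʳ ≥ *c* are superimposed on
   the PPI network via a gene→protein map.
3. **Coherence testing.** Three topology metrics of the selected set —
   % directly interacting proteins, % isolated nodes, and the largest
   connected component (LCC) size of the induced subgraph — are compared
   with *n* (default 1000) equal-size random protein sets; significance
   is empirical, *p̂* = (1 + r)/(n + 1), floor 1/1001 ≈ 0.001.
4. **Module extraction & evaluation.** The LCC gene set is benchmarked
   against a candidate list (precision/recall, with equal-count top-gene
   and all-at-cutoff controls) and across datasets (Jaccard overlap at
   SNP, gene and LCC level).
5. **Prioritization.** Primary-LCC proteins get a specificity score in
   [0, 1]: base 0.5, +0.5 if present in a replication dataset's LCC,
   −0.5/*K* per unrelated-disease LCC containing them (*K* = 6 by
   default). Score 1 = replicated and disease-specific.

A seeded synthetic-data generator (background ER/BA network + planted
connected module + Beta-enriched SNP p-values + overlapping candidate
list) makes every stage testable without access to restricted genotype
data.

## Worked example

```r
library(netnoise)

d <- simulate_dataset(synth_config(seed = 7))      # synthetic study
res <- run_pipeline(d$snps, d$genes, d$map, d$network, d$candidates,
                    config = list(cutoffs = c(0.5, 1, 1.5),
                                  n_perm = 1000, seed = 7))
print(res)
```

```
netnoise pipeline run
  SNPs: 29682   genes scored: 3000   network: 2000 proteins / 10017 edges
  LCC at -log10P >= 1: 109 proteins (109 genes) of 213 selected
  evaluation vs candidate list:
 selection_label n_selected n_hits precision_pct recall_pct
       lcc_genes        109     11     10.091743       27.5
       top_genes        109     13     11.926606       32.5
   all_at_cutoff        300     13      4.333333       32.5
```

The coherence scan shows why −log₁₀ *P* = 1 is the working cutoff:

```r
res$scan[, c("cutoff", "n_selected", "pct_direct", "lcc_size",
             "p_pct_direct", "p_lcc_size")]
```

```
 cutoff n_selected pct_direct lcc_size p_pct_direct  p_lcc_size
    0.5        649   95.83975      618  0.653346653 0.637362637
    1.0        213   73.70892      109  0.021978022 0.003996004
    1.5         74   63.51351       38  0.000999001 0.000999001
```

At the permissive 0.5 cutoff the selection is indistinguishable from
random sets (p ≈ 0.64); from cutoff 1.0 (*P* < 0.1) the 213 selected
proteins interact more than random expectation (p ≈ 0.022) and cohere in
a 109-protein LCC far larger than chance (p ≈ 0.004) — the planted
disease module surfacing from sub-threshold noise. The evaluation table
shows the LCC trade: against the 40-gene candidate list, LCC genes reach
10.1% precision versus 4.3% for all 300 genes at the same cutoff, at the
cost of recall (27.5% vs 32.5%).

Downstream, with a replication run `res2` and six unrelated-disease runs
`u1..u6`:

```r
sp <- score_proteins(res$lcc_proteins, res2$lcc_proteins,
                     list(u1$lcc_proteins, ..., u6$lcc_proteins))
top_gene_network(igraph::induced_subgraph(d$network, res$lcc_proteins),
                 sp, score_threshold = 1)
```

A thin command-line wrapper is included at `inst/scripts/netnoise.R`
(`simulate` and `run` subcommands). See the vignette
(`vignettes/network-gwas-noise.Rmd`) for the model, its assumptions, and
the generator's scope and limits.

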