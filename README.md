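# dmrpipe

Differential methylation analysis of tumor methylomes against a panel of
normal controls, with RNA-seq integration — for epigenomics groups analyzing
WGBS data of tumors (the design target is peripheral T-cell lymphoma-style
cohorts: a handful of near-identical normal methylomes, a handful of
heterogeneous tumors) who need per-tumor differentially methylated regions,
cross-tumor recurrence signatures, and the genes whose promoter methylation
plausibly drives their expression.

## The method

For each tumor, against the averaged control panel (sites covered ≥ 5x in
every sample):

* **DMC**: a CpG with methylation change |Δ| ≥ 10 percentage points
  (tumor − control mean).
* **DMR**: a maximal run of ≥ 3 consecutive same-direction DMCs with
  inter-CpG gaps ≤ 100 bp, kept when a two-sided Mann–Whitney U test of the
  tumor's per-CpG fractions against the pooled controls' per-CpG fractions
  over the region gives p < 0.05 (exact for small tie-free groups, tie-
  corrected normal approximation otherwise).

Downstream: DMRs are annotated to promoters (−1,500/+500 bp around the TSS,
strand-oriented), enhancers, exons, introns and repeats (1-bp overlap,
multi-hit counting); a **core methylation signature** collects the base-pair
intervals covered by same-direction DMRs in all tumors; expression uses
FPKM = count / (length<sub>kb</sub> × library<sub>millions</sub>), a
negative-binomial exceedance test per tumor versus averaged controls
(FC ≥ 1.5, p < 0.05), a **core expression signature** (≥ 2-fold in every
tumor), and an integrated gene list: hypomethylated promoter DMRs in ≥ 6 of
7 tumors plus expression up (≥ 2-fold, p < 0.05) in a majority of expression
tumors, and the hypermethylated/down mirror image.

A fully seeded simulator generates methylomes, annotations and counts with
planted hypo-/hypermethylated regions and promoter-coupled genes, emitting a
truth table for recovery scoring — every default is documented in the
methods vignette (`vignettes/methylation-pipeline.Rmd`).

## Worked example

```r
library(dmrpipe)
res <- run_pipeline(sim_config(seed = 7L), out_dir = "demo_run")
#> simulate: 40348 CpGs, 240 genes, 24 planted regions, 12 coupled genes
#> profile: 40348 CpGs covered >= 5x in all controls, min control R = 0.959
#> dmr: 60/60/71/69/74/66/71 DMRs per tumor
#> de: 27/31/33/27/36/25/30/43/33/29 significant genes per tumor
#> signature: 7 hypo / 3 hyper core regions; 5 up / 2 down core genes
#> integrate: 8 hypo-up and 4 hyper-down genes

head(res$integrated$hypo_up)
#>    gene_id hypo_count n_tumors_up   mean_fc
#> 1:  G1_020          7          10  7.404571
#> 2:  G1_040          7          10 11.350593
#> 3:  G1_066          6           8  7.591075
#> 4:  G1_076          6          10 16.895084
#> 5:  G2_020          7          10  9.496411
#> 6:  G2_023          6           8  5.955404
```

Reading the log: the 5 simulated controls are near-identical (pairwise
Pearson R ≥ 0.959 over all shared CpGs); each of the 7 tumors yields 60–74
DMRs (the 24 planted regions it carries plus minimal-width noise runs — see
the vignette on the select-then-test behavior); 7 hypo + 3 hyper core regions
recur in all seven tumors; and the integrated hypo-up list recovers exactly
the 8 genes whose promoters were planted hypomethylated with ~10-fold
expression coupling (`res$sim$truth$coupled_genes`), each with a promoter DMR
in ≥ 6 of 7 tumors and significant up-regulation in ≥ 8 of 10 expression
tumors. Every output lands in `demo_run/` as TSV/BED plus a `manifest.json`
with MD5 digests; re-running with the same seed reproduces every file bit
for bit.

The same stages are scriptable per-file via the CLI
(`inst/cli/dmrpipe simulate|profile|dmr|annotate|de|signature|run`).

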