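# tcburden

Ordering bulk tumor transcriptomes by global transcriptional activity.

Cross-sectional RNA-seq cohorts mix samples at unknown stages of disease.
`tcburden` stratifies such cohorts along a *transcriptomic burden* (TcB)
axis: for a harmonised log2 genes × samples matrix \(X\), each sample's
burden is the min–max rescaling (the field's "median shift",
`(value − range minimum)/range`) of its total log2 expression,

```
S_j  = Σ_i X_ij
TcB_j = (S_j − min_k S_k) / (max_k S_k − min_k S_k)  ∈ [0, 1]
```

Samples and genes are reordered by their scores ("abacus" ordering), samples
are banded as lowTcB ([0, 0.25]), midTcB ([0.375, 0.625]) and highTcB
([0.75, 1]) — gaps excluded — and the bands are compared by differential
expression (Welch t / Mann–Whitney, BH-FDR), Spearman screening of every gene
against the burden axis (|rho| > 0.75, p < 1e-4, top 50 per direction), and
local hypergeometric gene-set over-representation with higher-order pathway
collapsing. Paired initial/relapse designs are classified by upward burden
*band shifts*, and longitudinal designs yield per-subject burden courses
with per-timepoint gene-shift kernel densities. A synthetic generator with
planted gene programs, designated shifters and a treatment-reversal time
course makes the whole pipeline testable offline.

Intended users: computational biologists working with harmonised bulk
expression matrices (TPM/RPKM/FPKM/RSEM or pre-log2) who want a progression
axis without time-series data.

## Worked example

```r
library(tcburden)

sim    <- generate_progression_dataset(seed = 7)   # 120 samples x 2000 genes
tcb    <- compute_tcb(sim$matrix)
head(tcb, 3)
#>   sample_id  raw_sum         tcb
#> 1      S001 12037.26 0.000000000
#> 2      S002 12043.55 0.003184852
#> 3      S003 12086.62 0.024985191

groups <- assign_tcb_groups(tcb)
attr(groups, "counts")
#>      low      mid     high excluded
#>       30       29       31       30

de <- between_group_de(sim$matrix, groups, pair = c("low", "high"))
sum(de$significant)
#> [1] 100

enr <- hypergeometric_enrichment(de$gene_id[de$significant],
                                 rownames(sim$matrix), sim$sets)
head(enr[order(enr$p_value), c("set_name", "overlap", "p_value")], 1)
#>   set_name overlap       p_value
#> 1 ECM_LIKE     100 9.123576e-172

cor(tcb$tcb, sim$truth$samples$progression_index, method = "spearman")
#> [1] 0.9993819
```

The cohort's TcB ordering recovers the generator's hidden progression index
almost perfectly (Spearman 0.999); 30/29/31 samples land in the low/mid/high
bands with 30 in the guard gaps; the high-vs-low contrast flags exactly the
100 planted rising genes, and the over-representation test pins them to the
planted ECM-like module. (The planted *falling* program has a net gradient
of −1 on this dataset and sits below the 1.25 fold-change threshold — see
the methods vignette for why that is a property of the study conditions.)

One-command run over files, writing every stage's TSV plus a run manifest:

```r
run_pipeline("matrix.tsv", "results/", scale = "log2",
             metadata = "meta.tsv", sets = "sets.gmt",
             category_map = "categories.tsv")
```

or from a shell via the thin wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "tcburden.R", package = "tcburden"))') \
    run --matrix matrix.tsv --scale log2 --gmt sets.gmt --out results/
```

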