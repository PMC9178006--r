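# catchub

Cross-stage analysis of promoter H2AK119ub1 dynamics across the mouse
oocyte-to-embryo transition, from carrier-assisted (CATCH-seq-style)
low-input ChIP-seq.

H2AK119ub1 — monoubiquitinated histone H2A at lysine 119, deposited by
PRC1 and removed by deubiquitinases such as USP16 — accumulates at
promoters in fully grown (GV) oocytes, is largely erased by the mature
(MII) stage, and is re-established in two-cell embryos around zygotic
genome activation (ZGA). Quantifying those dynamics from a few hundred
cells poses two linked problems this package addresses for epigenomics
analysts:

1. **Cross-stage comparability without spike-ins.** Carrier-assisted ChIP
   produces a high, even genomic background. `catchub` exploits it:
   per-sample RPKM tracks (1 kb sliding bins, 200 bp steps) are rescaled
   so their 20%-trimmed-mean signal over random background regions
   matches a reference — equalizing assay efficiency across stages while
   preserving relative promoter signal.
2. **Stage-wise differential promoter enrichment.** Promoter (TSS ± 2 kb)
   read counts are tested per gene with a negative-binomial model:
   size-factor-normalized group means, method-of-moments dispersion
   moderated toward the across-gene median, and a Wald-type statistic
   `log2(FC) / SE` referenced against t with residual-plus-prior degrees
   of freedom. Benjamini–Hochberg-adjusted calls at `q < 0.05`,
   `|log2FC| > 1` define the gene sets "MII-ub-down", "two-cell-ub-down"
   and "cKO-MII-ub-up" (the Usp16-knockout retention set).

Around that core sit: a Poisson/BH broad-domain peak caller with the
quality filters RPKM ≥ 1 and width ≥ 800 bp; k-means co-occupancy
clustering of promoters by H3K4me3/H3K27me3/H2AK119ub1 signal; FPKM
gene-set logic (flooring at 1, ZGA defined by two-cell/zygote fold change
> 3, knockout up/down transcripts at fold change > 3, USP16-sensitive vs
-insensitive ZGA classes); strand-aware TSS metaplots against
size-matched random gene sets; and the absolute RT-qPCR ratio
`2^(Ct_g2 - Ct_g1) / [2^-(Ct1-Ct3) / 2^-(Ct2-Ct4)]` with
plasmid-standard primer-efficiency correction.

Everything is exercisable without external data through a synthetic-data
generator that plants ground truth (marked promoters per stage and
genotype, ZGA genes, USP16-sensitive genes) and emulates the statistical
structure of the real assay: high uniform background, enrichment-scaled
promoter domains, near-global erasure at MII with knockout retention, PCR
duplicates, replicate redraws and log-normal FPKM noise.

## Worked example

```r
library(catchub)

cfg <- pipeline_config(seed = 1)   # 300 genes, 150 GV-marked, 90% MII loss,
res <- run_pipeline(cfg)           # 5e5 reads/sample, 3 replicates

glance(res$diff$gv_vs_mii)
#> # A tibble: 1 × 4
#>   n_genes n_tested  n_up n_down
#>     <int>    <int> <int>  <int>
#> 1     300      300     0    135

set_venn(res$catalog)
#> # A tibble: 3 × 5
#>   set_a            set_b              n_a   n_b n_overlap
#>   <chr>            <chr>            <int> <int>     <int>
#> 1 MII-ub-down      two-cell-ub-down   135    30        30
#> 2 MII-ub-down      cKO-MII-ub-up      135   135       135
#> 3 two-cell-ub-down cKO-MII-ub-up       30   135        30

res$qpcr
#> # A tibble: 1 × 3
#>   efficiency_ratio relative_ratio absolute_ratio
#>              <dbl>          <dbl>          <dbl>
#> 1                1              5              5
```

The 135 genes called down between GV and MII are exactly the planted
mark-losing genes (the generator removed H2AK119ub1 from 90% of the 150
GV-marked promoters); all of them are recovered in the knockout contrast
as "cKO-MII-ub-up" (full retention in the knockout), and the 30
"two-cell-ub-down" genes nest inside "MII-ub-down", mirroring the
biology the model encodes. The qPCR table shows the noiseless
inverse-model identity: with equal primer efficiencies the relative and
absolute ratios coincide with the planted molar ratio of 5.

Individual stages are plain functions — e.g.

```r
study  <- simulate_study(cfg)
grid   <- bin_grid(study$ann)
tracks <- lapply(study$read_sets[1:2], build_track, grid = grid)
norm   <- background_normalize(tracks,
                               sample_random_regions(study$ann, seed = 1))
autoplot(tss_profile(norm[[1]], study$truth$zga_genes, study$ann))
```

`tidy()`, `glance()` and `autoplot()` methods cover the differential
results, clusterings and metaprofiles.

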