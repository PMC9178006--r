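---
title: "Models and methods behind catchub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind catchub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`catchub` analyzes promoter H2AK119ub1 dynamics across the
oocyte-to-embryo transition from low-input, carrier-assisted ChIP-seq,
together with the expression and qPCR readouts that surround that
question. This vignette explains the models, the parameters that matter,
the synthetic-data generator the tests run on, and the design choices
made where more than one reasonable option existed. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

```{r setup, eval = FALSE}
library(catchub)
```

## Coordinates and annotation model

All coordinates are 0-based half-open (BED convention) internally. A
gene's TSS is `start` on the plus strand and `end - 1` on the minus
strand; promoters are `[tss - flank, tss + flank)` with `flank = 2000`
bp by default, clipped at chromosome ends. Peak and interval
classification (TSS / TES / gene body / intergenic) uses the interval
midpoint with precedence TSS > TES > gene body, with ±2 kb zones around
the annotated sites: the assignment rule for such category tallies is
rarely stated in published work, and a midpoint-plus-precedence rule is
the simplest one that yields exactly one label per interval. One TSS per
gene is assumed; multi-isoform collapse is up to the annotation
supplied.

## Signal tracks and background-anchored normalization

Tracks are built on a sliding grid: tile *k* starts at `k * stepsize`
and spans `binsize` bp (defaults 200 bp and 1 kb — the standard choice
for broad histone marks, wide enough to stabilize counts, stepped finely
enough to localize domain edges). A read contributes to every tile
containing its midpoint; tile counts are scaled to RPKM
(`count / binsize[kb] / total_reads[M]`).

Carrier-assisted ChIP from hundreds of cells yields a high uniform
background. We treat that background as an internal standard: for each
sample the 20%-trimmed mean RPKM over tiles falling in a common set of
random regions (default 10,000 regions of 5 kb, drawn
length-proportionally and allowed to overlap genes — background
sampling should see the genome as it is) is computed, and every track is
rescaled to match the first track's background. The trimmed mean guards
against the minority of random regions that land on true signal; the
choice of reference sample only fixes a global unit. The scale is stored
as `background_scale` on each track and reused downstream. The
operation is idempotent and equalizes backgrounds to floating-point
accuracy, while ratios of promoter signal between samples are preserved
(verified against generator truth in the tests).

## Broad-domain peak calling

MACS2-style broad calling is re-implemented as a transparent
Poisson/Benjamini–Hochberg procedure: one global background rate λ (mean
tile count over the random background regions, or the genome-wide mean —
the analogue of calling with a global rather than local lambda), an
upper-tail Poisson p-value per tile, BH adjustment across tiles,
merging of significant tiles whose intervals are within `merge_gap`
(default 1 kb; an assumption, stated as such) and the printed quality
filters: peaks with mean RPKM < 1 or width < 800 bp are excluded. Read
extension is replaced by midpoint binning, a deliberate simplification
that only affects sub-bin resolution. On small tracks the caller is
bit-identical to a brute-force enumerate–threshold–merge–filter oracle
(an acceptance check), and lowering the q threshold can only shrink
peak-covered bases.

## Promoter differential enrichment

Promoter counts (read midpoints in TSS ± 2 kb, consistent with the tile
rule) feed a negative-binomial test per gene between two replicate
groups:

* **Size factors.** The classical median-of-ratios estimator is
  provided, but it assumes most genes unchanged. In cross-stage
  comparisons of an erased mark that assumption collapses (half the
  promoters change), so the pipeline instead uses background-anchored
  factors `total_reads / background_scale` (geometric mean 1): the same
  background that normalizes tracks normalizes the count model. Both
  estimators are exported; the choice is the user's.
* **Dispersion.** Per-gene pooled within-group method-of-moments
  (`var = mu + alpha * mu^2`), moderated toward the across-gene median
  with a prior weight of 10 pseudo-degrees of freedom. At 2–3 replicates
  the raw moment estimate is extremely noisy; moderation stabilizes the
  standard errors the way empirical-Bayes shrinkage does in established
  count-model packages, without importing their machinery. The floor of
  1e-8 keeps the Poisson limit well-defined.
* **Test.** `log2FC = log2(max(mean_B, pseudo) / max(mean_A, pseudo))`
  (a floor rather than an additive pseudo-count, so well-measured fold
  changes are exact and calls are invariant under rescaling a sample);
  standard error from the NB mean-variance relation by the delta
  method; reference distribution t with `n_A + n_B - 2 + prior_df`
  degrees of freedom — residual df augmented by the moderation prior,
  as in moderated-t practice. Under a pure NB null (mean 50, dispersion
  0.05, 3 vs 3) the fraction of p < 0.05 is ≈ 0.05 (computed in the
  acceptance suite), and a planted 8-fold decrease at mean 100 is
  recovered essentially completely.

Gene sets are then threshold sets: `q < 0.05` and `|log2FC| > 1` in the
stated direction, for the contrasts GV→MII (WT), GV→two-cell (WT) and
WT-MII vs cKO-MII. The thresholds are conventional and configurable —
the original analyses' exact cutoffs are not recoverable, so they are
surfaced in `pipeline_config()` rather than hard-coded.

## Co-occupancy clustering and enrichment

Promoter signals per mark are transformed `log2(x + 1)` (RPKM is
heavy-tailed) and z-scored per feature, then clustered with k-means:
k-means++ seeding, Lloyd iterations, best of 10 restarts by inertia,
deterministic per seed. Cluster labels are ordered by descending mean of
the first feature so that repeated runs report identically. Four groups
on (H3K4me3, H3K27me3) and five groups adding H2AK119ub1 are the
defaults. Gene-set enrichment per cluster is the fraction of the set in
the cluster, fold enrichment over the cluster's share of the universe,
and a hypergeometric upper-tail p-value, BH-adjusted across clusters.

## Expression gene-set logic

FPKM tables are floored before any fold change: genes below 1 in every
sample are dropped, remaining values below 1 are set to 1 — this is what
keeps near-zero denominators from fabricating large fold changes. On the
floored table: ZGA genes satisfy two-cell/zygote > 3 strictly; knockout
up/down transcripts satisfy cKO/WT > 3 or WT/cKO > 3; USP16-sensitive
ZGA genes are the intersection of the ZGA set with the knockout-down
set (set algebra, not a second statistical test), and the
sensitive/insensitive classes partition the ZGA set. Replicates are
aggregated by their mean before fold changes (median available); the
exclusion rule's "all samples" is read table-wide across stages and
genotypes.

## TSS metaplots

Profiles sample the normalized track at `TSS + offset` (plus strand) or
`TSS - offset` (minus strand), so positive offsets always face
downstream of transcription. The value at a position is the mean over
all sliding tiles covering it — a window symmetric around the position.
An earlier draft used the single tile starting at or before the
position; that rule is right-shifted by `(binsize - stepsize)/2` on
overlapping grids and visibly displaces domain apexes, which is why the
symmetric rule replaced it. Out-of-bounds offsets are dropped per gene
with the denominator tracked, avoiding edge bias on short chromosomes.
The default ±5 kb window covers the ±2 kb promoter with margin. Controls
are size-matched random gene sets drawn without replacement.

Note a geometric subtlety the tests respect: a flat-top domain wider
than the bin produces a plateau, not a peak — the profile maximum is
then uniformly distributed across the plateau offsets. The
peak-at-the-TSS check therefore plants domains exactly one bin wide,
whose expected profile is triangular with its apex at offset 0.

## Absolute RT-qPCR ratios

With one Ct unit per template doubling: the primer-efficiency ratio of
the two gene assays is `2^-(Ct1-Ct3) / 2^-(Ct2-Ct4)` from the two
plasmid standards (each carrying one gene fragment plus a shared Gfp
reference), the relative transcript ratio is
`2^-(Ct_g1-Ct_ref) / 2^-(Ct_g2-Ct_ref) = 2^(Ct_g2-Ct_g1)` (the Gapdh
reference cancels), and the absolute ratio divides the relative ratio by
the efficiency ratio. Replicates are averaged on the Ct scale — the
measurement scale — which equals taking geometric means of the derived
quantities. The amplification base is fixed at 2; no standard-curve
slope fitting is attempted.

## The synthetic study and what it does (not) show

`simulate_study()` plants: 300 genes on three 5 Mb chromosomes (genes
spaced so promoters never overlap); 150 GV-marked promoters of which 90%
lose the mark by MII in wild type and none in the knockout (retention);
a two-cell state where 20% of GV-marked genes stay unmarked, nested
inside the MII-lost set; 60 ZGA genes drawn from promoters unmarked at
the two-cell stage, half USP16-sensitive; H3K4me3 (narrow, linked to a
10× expression boost) and H3K27me3 (broad, co-occurring with
H2AK119ub1 at rate 0.7 vs 0.1 elsewhere) in GV. Reads: 5×10⁵ per sample,
50 bp, 10% exact-copy PCR duplicates, three i.i.d. replicate redraws per
condition.

Read allocation is enrichment-conserving by default: a marked domain's
read rate is `enrichment` (default 20) times the genome-wide background
rate, so the uniform background share is `G / (G + m(E-1)w)` — about
57% of reads at GV and about 93% at MII, rising as marks are erased,
exactly the regime the background-anchored normalization is built for.
Passing a numeric `background_fraction` instead fixes the uniform share
directly and turns `enrichment` into a per-gene allocation weight; that
mode exists for controlled experiments (uniformity checks, limit cases)
but does not conserve per-gene signal when the marked set changes size,
so it is not the cross-stage default.

Passing tests on this generator demonstrates internal correctness —
parameter recovery under the model's own assumptions — not performance
on real data: there is no sequence, no mappability or GC structure, no
carrier-species mixture, domains are rectangles centered on the TSS,
replicates are exchangeable, and FPKM noise is log-normal. Simulation
sizes (300 genes, 5×10⁵ reads, 10 null replications of 2,000 promoters,
200 oracle tracks) were chosen as the smallest at which the planted
effects are comfortably identifiable with stable test statistics.

## Reproducibility mechanics

All generators and the clustering are pure functions of (parameters,
seed); RNG state is saved and restored around every seeded operation, so
library calls never perturb a caller's stream. `run_pipeline()` derives
one sub-seed per stage from the root seed, writes every table
deterministically, and emits a manifest with the package version, seeds
and a config hash: identical configs give byte-identical outputs, which
the acceptance suite verifies by checksum. Degenerate inputs error
early and descriptively: zero-background tracks cannot be normalized or
peak-called, constant features cannot be z-scored, k above the number
of distinct rows cannot be clustered, re-flooring a floored table is
refused, and empty gene sets are rejected where a profile or enrichment
would be meaningless.
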