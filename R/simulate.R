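#' Simulate a toy genome annotation
#'
#' Places non-overlapping genes with random strands on equal-length
#' chromosomes, spaced so that no two promoters (TSS +/- `flank`) overlap.
#' Gene starts within a chromosome are a sorted uniform draw over the slack
#' left after reserving one gene-plus-flanks block per gene.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Total gene count.
#' @param gene_length Gene length in bp.
#' @param flank Promoter flank reserved around each TSS (bp).
#' @param seed RNG seed.
#' @return A `genome_annotation`.
#' @export
simulate_genome <- function(n_chrom = 3, chrom_length = 5e6, n_genes = 300,
                            gene_length = 2000, flank = 2000, seed = 1) {
  chrom <- tibble(chrom = sprintf("chr%d", seq_len(n_chrom)),
                  length = rep(chrom_length, n_chrom))
  per <- rep(floor(n_genes / n_chrom), n_chrom)
  extra <- n_genes - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  block <- gene_length + 2 * flank
  if (any(per * block + 2 * flank > chrom_length)) {
    abort("infeasible packing: too many genes for the genome size")
  }
  with_seed_(seed, {
    genes <- purrr::map2(seq_len(n_chrom), per, function(ci, nc) {
      if (nc == 0) return(NULL)
      slack <- chrom_length - 2 * flank - nc * block
      u <- sort(runif(nc, 0, slack))
      start <- floor(flank + (seq_len(nc) - 1) * block + u)
      tibble(chrom = chrom$chrom[ci], start = start,
             end = start + gene_length,
             strand = sample(c("+", "-"), nc, replace = TRUE))
    }) |> bind_rows()
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    genome_annotation(genes, chrom)
  })
}

#' Plant ground-truth mark and gene-set structure on a genome
#'
#' Encodes the biology the pipeline is built to detect: H2AK119ub1 broadly
#' deposited at a subset of promoters in GV oocytes, largely erased by MII
#' in wild type but fully retained in the maternal Usp16 knockout (cKO),
#' and partially re-established at the two-cell stage; H3K4me3 (narrow,
#' active) and H3K27me3 (broad, repressive) with structured overlap in GV;
#' ZGA genes drawn from promoters unmarked at the two-cell stage, a subset
#' of which is USP16-sensitive.
#'
#' @param ann A `genome_annotation`.
#' @param n_marked_gv Genes carrying H2AK119ub1 in GV oocytes.
#' @param mii_loss Fraction of GV-marked genes losing the mark at MII in
#'   wild type.
#' @param cko_mii_loss Same fraction in the cKO (0 = full retention).
#' @param twocell_off_frac Fraction of GV-marked genes that remain unmarked
#'   at the two-cell stage (drawn from the MII-lost genes, so the two-cell
#'   loss set nests inside the MII loss set).
#' @param n_zga Number of ZGA genes (activated zygote -> two-cell).
#' @param sensitive_frac Fraction of ZGA genes that are USP16-sensitive.
#' @param n_k4 Genes carrying H3K4me3 in GV.
#' @param k27_given_ub,k27_base Probability a gene carries H3K27me3 in GV,
#'   given it is/is not ub-marked (structured co-occupancy).
#' @param seed RNG seed.
#' @return A `sim_truth` list: `marked[[mark]][[genotype]][[stage]]`
#'   character vectors, `zga_genes`, `usp16_sensitive`, and the seed.
#' @export
simulate_truth <- function(ann, n_marked_gv = 150, mii_loss = 0.9,
                           cko_mii_loss = 0, twocell_off_frac = 0.2,
                           n_zga = 60, sensitive_frac = 0.5,
                           n_k4 = 150, k27_given_ub = 0.7, k27_base = 0.1,
                           seed = 1) {
  genes <- ann$gene_id
  with_seed_(seed, {
    gv <- sample(genes, n_marked_gv)
    n_lost <- round(mii_loss * n_marked_gv)
    mii_lost <- sample(gv, n_lost)
    mii_wt <- setdiff(gv, mii_lost)
    cko_lost <- sample(mii_lost, round(cko_mii_loss / max(mii_loss, 1e-12) *
                                         n_lost))
    mii_cko <- setdiff(gv, cko_lost)
    n_off <- round(twocell_off_frac * n_marked_gv)
    twocell_off <- sample(mii_lost, min(n_off, length(mii_lost)))
    twocell <- setdiff(gv, twocell_off)
    zga <- sample(setdiff(genes, twocell), n_zga)
    sens <- sample(zga, round(sensitive_frac * n_zga))
    k4 <- sample(genes, n_k4)
    is_ub <- genes %in% gv
    k27 <- genes[runif(length(genes)) <
                   ifelse(is_ub, k27_given_ub, k27_base)]
    truth <- list(
      marked = list(
        H2AK119ub1 = list(
          WT = list(GV = gv, MII = mii_wt, twocell = twocell),
          cKO = list(GV = gv, MII = mii_cko)
        ),
        H3K4me3 = list(WT = list(GV = k4)),
        H3K27me3 = list(WT = list(GV = k27))
      ),
      zga_genes = zga,
      usp16_sensitive = sens,
      seed = seed
    )
    class(truth) <- "sim_truth"
    truth
  })
}

#' Marked-gene set from a `sim_truth`
#' @param truth A `sim_truth`.
#' @param mark,stage,genotype Condition selectors.
#' @return Character vector of gene ids.
#' @export
marked_genes <- function(truth, mark = "H2AK119ub1", stage = "GV",
                         genotype = "WT") {
  out <- truth$marked[[mark]][[genotype]][[stage]]
  if (is.null(out)) abort(sprintf("no planted set for %s/%s/%s",
                                  mark, genotype, stage))
  out
}

#' Simulate an aligned-read interval set for one ChIP sample
#'
#' Emulates carrier-assisted ChIP: a high uniform background over the whole
#' genome with the remaining reads falling in fixed-width promoter domains
#' centered on the TSS of the marked genes. By default
#' (`background_fraction = NULL`) the uniform/domain split is derived from
#' `enrichment`: each marked domain's read rate is `enrichment` times the
#' genome-wide background rate, so the per-gene signal is conserved when
#' the number of marked genes changes between stages (as in near-global
#' erasure), and the realized background share rises as marks are lost.
#' Supplying a numeric `background_fraction` instead fixes the uniform
#' share of reads directly; the remainder is then split across marked
#' genes proportionally to `enrichment` used as a weight. PCR duplicates
#' are injected as exact coordinate copies at rate `dup_rate` (so
#' `depth * (1 - dup_rate)` reads are drawn independently).
#'
#' @param ann A `genome_annotation`.
#' @param marked Character vector of marked gene ids (may be empty).
#' @param depth Total reads including duplicates.
#' @param background_fraction `NULL` (enrichment-derived split) or the
#'   fixed fraction of unique reads drawn uniformly.
#' @param enrichment Fold enrichment of a marked domain over background
#'   (scalar or one per marked gene).
#' @param domain_width Width of the marked promoter domain (bp).
#' @param read_length Read length (bp).
#' @param dup_rate Fraction of reads that are duplicate copies.
#' @param seed RNG seed.
#' @param stage,genotype,mark,replicate Sample metadata recorded on the
#'   result.
#' @return A `read_set`: tibble (`chrom`, `start`, `end`, `strand`) with
#'   metadata attributes.
#' @export
simulate_reads <- function(ann, marked, depth = 5e5,
                           background_fraction = NULL, enrichment = 20,
                           domain_width = 4000, read_length = 50,
                           dup_rate = 0.1, seed = 1,
                           stage = NA_character_, genotype = NA_character_,
                           mark = NA_character_, replicate = 1L) {
  if (depth <= 0) abort("`depth` must be positive")
  chrom <- chromosomes(ann)
  e <- rep_len(enrichment, length(marked))
  with_seed_(seed, {
    n_unique <- round(depth * (1 - dup_rate))
    if (length(marked) == 0) {
      n_sig <- 0L
    } else if (is.null(background_fraction)) {
      # domain rate = enrichment x background rate: the uniform share is
      # G / (G + sum (e-1) * w) of all reads
      genome_bp <- sum(chrom$length)
      extra <- sum(pmax(e - 1, 0)) * domain_width
      n_sig <- round(n_unique * extra / (genome_bp + extra))
    } else {
      n_sig <- round(n_unique * (1 - background_fraction))
    }
    n_bg <- n_unique - n_sig

    ci <- sample.int(nrow(chrom), n_bg, replace = TRUE,
                     prob = chrom$length)
    bg_start <- floor(runif(n_bg, 0, chrom$length[ci] - read_length))
    bg <- tibble(chrom = chrom$chrom[ci], start = bg_start)

    if (n_sig > 0) {
      m <- ann[match(marked, ann$gene_id), ]
      w <- if (is.null(background_fraction)) pmax(e - 1, 0) else e
      gi <- sample.int(length(marked), n_sig, replace = TRUE, prob = w)
      lo <- m$tss[gi] - domain_width / 2
      hi <- m$tss[gi] + domain_width / 2 - read_length
      len <- chrom$length[match(m$chrom[gi], chrom$chrom)]
      start <- floor(runif(n_sig, pmax(0, lo), pmin(hi, len - read_length)))
      sig <- tibble(chrom = m$chrom[gi], start = start)
      reads <- bind_rows(bg, sig)
    } else {
      reads <- bg
    }
    reads$end <- reads$start + read_length
    reads$strand <- sample(c("+", "-"), nrow(reads), replace = TRUE)

    n_dup <- depth - n_unique
    if (n_dup > 0) {
      reads <- bind_rows(reads,
                         reads[sample.int(nrow(reads), n_dup,
                                          replace = TRUE), ])
    }
    reads <- arrange(reads, .data$chrom, .data$start, .data$end,
                     .data$strand)
    new_read_set(reads, stage = stage, genotype = genotype, mark = mark,
                 replicate = replicate, read_length = read_length)
  })
}

new_read_set <- function(reads, stage, genotype, mark, replicate,
                         read_length) {
  attr(reads, "meta") <- list(stage = stage, genotype = genotype,
                              mark = mark, replicate = replicate)
  attr(reads, "read_length") <- read_length
  class(reads) <- unique(c("read_set", class(reads)))
  reads
}

#' Metadata of a read set
#' @param reads A `read_set`.
#' @return A list with `stage`, `genotype`, `mark`, `replicate`.
#' @export
read_meta <- function(reads) {
  attr(reads, "meta") %||% list(stage = NA, genotype = NA, mark = NA,
                                replicate = NA)
}

#' Simulate a replicated FPKM expression table
#'
#' Non-ZGA genes get a stage- and genotype-invariant baseline drawn from a
#' log-normal; H3K4me3-marked genes are shifted up (active promoters). ZGA
#' genes are near-silent (`zga_low`) until the two-cell stage, where they
#' rise to `zga_high` in wild type; USP16-sensitive ZGA genes stay low in
#' the cKO at the two-cell stage. Multiplicative log-normal noise with
#' log-scale standard deviation `noise_sd` is applied per replicate.
#'
#' @param ann A `genome_annotation`.
#' @param truth A `sim_truth`.
#' @param noise_sd Log-scale noise SD (0 = deterministic table).
#' @param n_reps Replicates per condition.
#' @param stages Stages to emit.
#' @param genotypes Genotypes to emit.
#' @param zga_low,zga_high Pre/post-activation FPKM of ZGA genes.
#' @param k4_boost Fold applied to H3K4me3-marked genes' baseline.
#' @param seed RNG seed.
#' @return An `expression_table`: long tibble (`gene_id`, `stage`,
#'   `genotype`, `replicate`, `fpkm`) with a `floored` attribute of FALSE.
#' @export
simulate_expression <- function(ann, truth, noise_sd = 0.2, n_reps = 3,
                                stages = c("GV", "zygote", "twocell"),
                                genotypes = c("WT", "cKO"),
                                zga_low = 0.25, zga_high = 8,
                                k4_boost = 10, seed = 1) {
  genes <- ann$gene_id
  k4 <- genes %in% marked_genes(truth, "H3K4me3", "GV", "WT")
  zga <- genes %in% truth$zga_genes
  sens <- genes %in% truth$usp16_sensitive
  with_seed_(seed, {
    base <- exp(rnorm(length(genes), log(5), 1)) * ifelse(k4, k4_boost, 1)
    grid <- tidyr::expand_grid(stage = stages, genotype = genotypes,
                               replicate = seq_len(n_reps))
    tab <- purrr::pmap(grid, function(stage, genotype, replicate) {
      mu <- base
      mu[zga] <- if (stage == "twocell") zga_high else zga_low
      if (stage == "twocell" && genotype == "cKO") {
        mu[sens] <- zga_high / 8
      }
      fpkm <- mu * exp(rnorm(length(genes), 0, noise_sd))
      tibble(gene_id = genes, stage = stage, genotype = genotype,
             replicate = replicate, fpkm = fpkm)
    }) |> bind_rows()
    new_expression_table(tab, floored = FALSE)
  })
}

new_expression_table <- function(tab, floored) {
  attr(tab, "floored") <- floored
  class(tab) <- unique(c("expression_table", class(tab)))
  tab
}

#' Simulate a labeled Ct table for the absolute-ratio assay
#'
#' Generates plasmid-standard Cts (gene-specific primers vs Gfp primers on
#' the same plasmid) with primer-efficiency ratio
#' `efficiencies[1]/efficiencies[2]`, and sample Cts whose Gapdh-referenced
#' relative ratio equals `true_ratio` times that efficiency ratio — so the
#' efficiency-corrected absolute ratio recovers `true_ratio`. One Ct unit
#' corresponds to one template doubling; Gaussian noise of SD `noise_sd` is
#' added per replicate measurement.
#'
#' @param true_ratio True molar mRNA ratio of gene 1 over gene 2.
#' @param efficiencies Length-2 vector of relative primer efficiencies.
#' @param ct_ref Sample Gapdh Ct.
#' @param noise_sd Gaussian Ct noise SD.
#' @param n_reps Replicate measurements per quantity.
#' @param seed RNG seed.
#' @return A `ct_table`: long tibble (`quantity`, `replicate`, `ct`) with
#'   quantities `ct1`..`ct4`, `ct_g1`, `ct_g2`, `ct_ref`.
#' @export
simulate_qpcr <- function(true_ratio = 5, efficiencies = c(1, 1),
                          ct_ref = 18, noise_sd = 0, n_reps = 3, seed = 1) {
  if (true_ratio <= 0) abort("`true_ratio` must be positive")
  if (any(efficiencies <= 0)) abort("efficiencies must be positive")
  eff_ratio <- efficiencies[1] / efficiencies[2]
  relative <- true_ratio * eff_ratio
  ct <- c(ct1 = 20 - log2(efficiencies[1]),
          ct2 = 20 - log2(efficiencies[2]),
          ct3 = 20, ct4 = 20,
          ct_g1 = 25 - log2(relative), ct_g2 = 25,
          ct_ref = ct_ref)
  with_seed_(seed, {
    tab <- tidyr::expand_grid(quantity = names(ct),
                              replicate = seq_len(n_reps)) |>
      mutate(ct = ct[.data$quantity] +
               rnorm(dplyr::n(), 0, noise_sd))
    attr(tab, "true_ratio") <- true_ratio
    class(tab) <- unique(c("ct_table", class(tab)))
    tab
  })
}
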