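#' Configuration for the gene-drop study simulator
#'
#' Bundles every tunable of the synthetic study: pedigree structure,
#' variant map shape, the minor-allele-frequency law, the liability-scale
#' phenotype model, and replicate count. Defaults emulate the shape of
#' a mini-exome family study: eight extended pedigrees of five
#' generations totalling roughly 700 individuals, 24,488 SNPs in 3,205
#' genes with a rare-heavy frequency spectrum (~88% of SNPs with
#' MAF < 0.1, ~37% nonsynonymous), and 200 phenotype replicates over a
#' single fixed genotype set. Everything scales down for testing.
#'
#' @param n_pedigrees Number of extended pedigrees.
#' @param depth Generations per pedigree (>= 2; default 5 so that pairs up
#'   to fifth degree — second cousins — exist).
#' @param n_genes,n_snps Genes and SNPs in the variant map; every gene
#'   receives at least one SNP, so `n_snps >= n_genes` is required.
#' @param chromosomes Tibble (`chrom`, `length_cM`) of chromosome genetic
#'   lengths; default: 22 autosomes with approximate sex-averaged lengths
#'   (~3,400 cM total).
#' @param maf_shape1,maf_shape2,maf_min Parameters of the MAF law: a
#'   Beta(shape1, shape2) truncated to `[maf_min, 0.5]`. The default
#'   Beta(0.2, 8) puts ~88% of the mass below 0.1, matching the rare-heavy
#'   spectrum of exome panels.
#' @param prop_nonsyn Fraction of SNPs labelled nonsynonymous
#'   (default 8994/24488).
#' @param n_causal_genes Genes planted with causal variants.
#' @param causal_effect Liability-scale effect per minor allele at each
#'   causal variant (units of the residual SD).
#' @param causal_maf_max Population-MAF ceiling for causal variants: the
#'   risk alleles of a causal gene are its nonsynonymous SNPs with
#'   `maf < causal_maf_max` (default 0.05) — rare alleles, the regime a
#'   family-based IBD design can detect.
#' @param causal_min_carriers Causal genes are drawn among genes where
#'   such a rare risk allele is carried by at least this many individuals
#'   (default 20): a rare allele enriched by descent from a founder, so
#'   that affected carriers form identity-by-descent clusters. Genes whose
#'   rare alleles did not segregate cannot be recovered by any
#'   family-based method.
#' @param prevalence Target affected fraction per replicate, in (0, 1).
#' @param n_replicates Phenotype replicates drawn over the one genotype
#'   set.
#' @param mean_children Mean children per mated couple (children are drawn
#'   as `3 + Binomial(2, (mean_children - 3) / 2)`, so 3 to 5).
#' @param seed Optional integer seed; when set, [simulate_study()] is
#'   fully reproducible.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_pedigrees = 2, n_genes = 100, n_snps = 600,
#'                   n_replicates = 10, seed = 42)
#' @export
sim_config <- function(n_pedigrees = 8,
                       depth = 5,
                       n_genes = 3205,
                       n_snps = 24488,
                       chromosomes = default_chromosomes(),
                       maf_shape1 = 0.2,
                       maf_shape2 = 8,
                       maf_min = 5e-4,
                       prop_nonsyn = 8994 / 24488,
                       n_causal_genes = 5,
                       causal_effect = 1,
                       causal_maf_max = 0.05,
                       causal_min_carriers = 20,
                       prevalence = 0.20,
                       n_replicates = 200,
                       mean_children = 3.2,
                       seed = NULL) {
  cfg <- list(
    n_pedigrees = as.integer(n_pedigrees), depth = as.integer(depth),
    n_genes = as.integer(n_genes), n_snps = as.integer(n_snps),
    chromosomes = as_tibble(chromosomes),
    maf_shape1 = maf_shape1, maf_shape2 = maf_shape2, maf_min = maf_min,
    prop_nonsyn = prop_nonsyn,
    n_causal_genes = as.integer(n_causal_genes),
    causal_effect = causal_effect, causal_maf_max = causal_maf_max,
    causal_min_carriers = as.integer(causal_min_carriers),
    prevalence = prevalence,
    n_replicates = as.integer(n_replicates),
    mean_children = mean_children,
    seed = if (!is.null(seed)) as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_pedigrees", "n_genes", "n_snps", "n_replicates")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      abort(paste0(f, " must be a positive count"))
    }
  }
  if (cfg$depth < 2) abort("depth must be >= 2 (no transmissions otherwise)")
  if (cfg$n_snps < cfg$n_genes) {
    abort("n_snps must be >= n_genes (every gene needs at least one SNP)")
  }
  if (!(cfg$prevalence > 0 && cfg$prevalence < 1)) {
    abort("prevalence must lie in (0, 1)")
  }
  if (cfg$n_causal_genes < 0 || cfg$n_causal_genes > cfg$n_genes) {
    abort("n_causal_genes must lie in [0, n_genes]")
  }
  if (!(cfg$causal_maf_max > 0 && cfg$causal_maf_max <= 0.5)) {
    abort("causal_maf_max must lie in (0, 0.5]")
  }
  if (cfg$causal_min_carriers < 0) {
    abort("causal_min_carriers must be non-negative")
  }
  chr <- cfg$chromosomes
  if (!all(c("chrom", "length_cM") %in% names(chr)) || nrow(chr) == 0 ||
      any(chr$length_cM < 0)) {
    abort("chromosomes must be a tibble with columns chrom, length_cM >= 0")
  }
  if (!(cfg$mean_children >= 3 && cfg$mean_children <= 5)) {
    abort("mean_children must lie in [3, 5]")
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_chromosomes <- function() {
  tibble(
    chrom = as.character(1:22),
    length_cM = c(278, 263, 224, 214, 209, 194, 187, 169, 167, 174, 161,
                  176, 131, 125, 132, 134, 138, 126, 110, 114, 68, 79)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d pedigrees x depth %d; %d genes / %d SNPs on %d chromosomes\n",
              x$n_pedigrees, x$depth, x$n_genes, x$n_snps, nrow(x$chromosomes)))
  cat(sprintf("  MAF ~ Beta(%.2g, %.2g) on [%.4g, 0.5]; %.1f%% nonsynonymous\n",
              x$maf_shape1, x$maf_shape2, x$maf_min, 100 * x$prop_nonsyn))
  cat(sprintf("  %d causal genes, effect %.2g per allele, prevalence %.2f, %d replicates\n",
              x$n_causal_genes, x$causal_effect, x$prevalence, x$n_replicates))
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
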