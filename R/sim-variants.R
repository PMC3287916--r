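#' Simulate an exome-like variant map
#'
#' Lays genes out along the configured chromosomes (allocated
#' proportionally to genetic length), treats each gene as a point locus at
#' its cM midpoint, and scatters SNPs into genes (each gene gets at least
#' one). Minor allele frequencies are drawn from a truncated
#' Beta(`maf_shape1`, `maf_shape2`) on `[maf_min, 0.5]` — rare-heavy by
#' default — and each SNP is labelled synonymous or nonsynonymous with
#' probability `prop_nonsyn` of the latter. Physical positions are derived
#' from the genetic map at 1 Mb/cM with SNPs of a gene packed around the
#' gene midpoint, strictly increasing along each chromosome.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per SNP: `snp`, `chrom`, `pos_bp`,
#'   `pos_cM`, `gene`, `maf`, `func` (`"synonymous"`/`"nonsynonymous"`).
#'   The per-gene layout (gene midpoints) is attached as attribute
#'   `"genes"` (tibble `gene`, `chrom`, `pos_cM`).
#' @examples
#' map <- sim_variant_map(sim_config(n_genes = 10, n_snps = 50, seed = 1))
#' mean(map$maf < 0.1)
#' @export
sim_variant_map <- function(config) {
  validate_sim_config(config)
  maybe_with_seed(config$seed, sim_variant_map_impl(config))
}

sim_variant_map_impl <- function(config) {
  chr <- config$chromosomes
  n_genes <- config$n_genes
  n_snps <- config$n_snps

  # genes per chromosome, proportional to length (largest-remainder
  # rounding); uniform when all lengths are zero
  w <- if (sum(chr$length_cM) > 0) {
    chr$length_cM / sum(chr$length_cM)
  } else {
    rep(1 / nrow(chr), nrow(chr))
  }
  base <- floor(w * n_genes)
  rem <- n_genes - sum(base)
  if (rem > 0) {
    extra <- order(w * n_genes - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }

  genes <- purrr::map_dfr(seq_len(nrow(chr)), function(i) {
    k <- base[i]
    if (k == 0) return(NULL)
    tibble(chrom = chr$chrom[i],
           pos_cM = sort(runif(k, 0, chr$length_cM[i])))
  })
  genes$gene <- sprintf("G%0*d", nchar(n_genes), seq_len(nrow(genes)))
  genes <- genes[c("gene", "chrom", "pos_cM")]

  # SNPs per gene: one guaranteed, the rest multinomial
  snp_per_gene <- rep(1L, n_genes)
  spare <- n_snps - n_genes
  if (spare > 0) {
    snp_per_gene <- snp_per_gene +
      as.integer(stats::rmultinom(1, spare, rep(1, n_genes)))
  }

  gene_idx <- rep(seq_len(n_genes), snp_per_gene)
  within <- sequence(snp_per_gene)
  map <- tibble(
    chrom = genes$chrom[gene_idx],
    pos_cM = genes$pos_cM[gene_idx],
    gene = genes$gene[gene_idx]
  )
  # bp: 1 Mb per cM, SNPs spaced 100 bp within their gene
  map$pos_bp <- round(map$pos_cM * 1e6) + (within - 1L) * 100L + 1L
  map <- map |> arrange(.data$chrom, .data$pos_bp)
  # guard against midpoint collisions between adjacent genes
  map <- map |>
    group_by(.data$chrom) |>
    mutate(pos_bp = fix_increasing(.data$pos_bp)) |>
    ungroup()
  map <- map |>
    group_by(.data$chrom) |>
    mutate(snp = sprintf("C%sS%d", .data$chrom[1], row_number())) |>
    ungroup()

  map$maf <- rtrunc_beta(nrow(map), config$maf_shape1, config$maf_shape2,
                         config$maf_min, 0.5)
  map$func <- ifelse(runif(nrow(map)) < config$prop_nonsyn,
                     "nonsynonymous", "synonymous")
  map <- map[c("snp", "chrom", "pos_bp", "pos_cM", "gene", "maf", "func")]
  attr(map, "genes") <- genes
  map
}

# strictly increasing integer positions, minimally perturbed
fix_increasing <- function(x) {
  if (length(x) < 2) return(x)
  for (i in 2:length(x)) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + 1L
  x
}

# inverse-CDF sampling from Beta(a, b) truncated to [lo, hi]
rtrunc_beta <- function(n, a, b, lo, hi) {
  u <- runif(n, pbeta(lo, a, b), pbeta(hi, a, b))
  qbeta(u, a, b)
}

#' Gene layout of a variant map
#'
#' @param map A variant map from [sim_variant_map()] (or any map tibble
#'   with a `"genes"` attribute; otherwise the layout is reconstructed
#'   from the SNP rows by taking each gene's median cM position).
#' @return Tibble `gene`, `chrom`, `pos_cM`.
#' @export
gene_layout <- function(map) {
  g <- attr(map, "genes")
  if (!is.null(g)) return(g)
  map |>
    group_by(.data$gene) |>
    summarise(chrom = .data$chrom[1],
              pos_cM = stats::median(.data$pos_cM), .groups = "drop") |>
    select("gene", "chrom", "pos_cM")
}
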