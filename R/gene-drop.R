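#' Gene-drop simulation of founder-labelled genomes
#'
#' Transmits uniquely labelled founder haplotypes down each pedigree.
#' Every founder carries two unique labels per chromosome; every
#' nonfounder inherits one recombined haplotype from each parent, with
#' crossover counts Poisson(length/100 cM) and crossover positions uniform
#' (Haldane's no-interference model). Genes are point loci at their cM
#' midpoints, so each individual holds exactly two founder labels per
#' gene; identity of labels between individuals is identity by descent.
#' Founder haplotypes are then filled with alleles drawn per SNP from its
#' minor allele frequency, and genotypes are reported as minor-allele
#' dosages (0/1/2).
#'
#' @param pedigree A pedigree tibble (see [as_pedigree()]).
#' @param map A variant map from [sim_variant_map()] (or any tibble with
#'   columns `snp`, `chrom`, `pos_cM`, `gene`, `maf`).
#' @param chromosomes Tibble (`chrom`, `length_cM`); defaults to the
#'   lengths implied by [default_chromosomes()] restricted to the
#'   chromosomes present in `map`.
#' @param seed Optional seed for reproducibility.
#' @return An object of class `gene_drop`: a list with
#'   * `labels_pat`, `labels_mat` — integer matrices (individuals x genes)
#'     of founder haplotype labels,
#'   * `dosage` — integer matrix (individuals x SNPs) of minor-allele
#'     counts,
#'   * `founder_haps` — tibble mapping labels to founder ids,
#'   * `genes`, `snps`, `ids` — the dimension names.
#' @examples
#' cfg <- sim_config(n_pedigrees = 1, n_genes = 20, n_snps = 60, seed = 3)
#' ped <- sim_pedigrees(cfg)
#' map <- sim_variant_map(cfg)
#' drop <- gene_drop(ped, map, cfg$chromosomes, seed = 3)
#' dim(drop$dosage)
#' @export
gene_drop <- function(pedigree, map, chromosomes = NULL, seed = NULL) {
  pedigree <- as_pedigree(pedigree)
  genes <- gene_layout(map)
  if (is.null(chromosomes)) {
    chromosomes <- default_chromosomes()
    chromosomes <- chromosomes[chromosomes$chrom %in% genes$chrom, ]
  }
  missing_chr <- setdiff(genes$chrom, chromosomes$chrom)
  if (length(missing_chr) > 0) {
    abort(paste0("no chromosome length for: ", paste(missing_chr, collapse = ", ")))
  }
  maybe_with_seed(seed, gene_drop_impl(pedigree, map, genes, chromosomes))
}

gene_drop_impl <- function(pedigree, map, genes, chromosomes) {
  n_ind <- nrow(pedigree)
  n_genes <- nrow(genes)
  ids <- pedigree$id
  idx <- setNames(seq_len(n_ind), ids)

  # gene indices grouped by chromosome, in map order
  chr_of_gene <- genes$chrom
  gene_sets <- split(seq_len(n_genes), chr_of_gene)
  chr_len <- setNames(chromosomes$length_cM, chromosomes$chrom)

  lab_pat <- matrix(0L, n_ind, n_genes, dimnames = list(ids, genes$gene))
  lab_mat <- lab_pat

  founders <- which(pedigree$founder)
  # founder f carries labels 2f-1 (paternal slot) and 2f
  f_rank <- integer(n_ind)
  f_rank[founders] <- seq_along(founders)
  lab_pat[founders, ] <- 2L * f_rank[founders] - 1L
  lab_mat[founders, ] <- 2L * f_rank[founders]

  nonf <- which(!pedigree$founder)   # topological order preserved
  for (i in nonf) {
    lab_pat[i, ] <- meiosis_labels(lab_pat[idx[pedigree$father[i]], ],
                                   lab_mat[idx[pedigree$father[i]], ],
                                   genes$pos_cM, gene_sets, chr_len)
    lab_mat[i, ] <- meiosis_labels(lab_pat[idx[pedigree$mother[i]], ],
                                   lab_mat[idx[pedigree$mother[i]], ],
                                   genes$pos_cM, gene_sets, chr_len)
  }

  # founder haplotype alleles: one Bernoulli(maf) draw per (haplotype, SNP)
  n_haps <- 2L * length(founders)
  n_snps <- nrow(map)
  hap_alleles <- matrix(
    rbinom(n_haps * n_snps, 1L, rep(map$maf, each = n_haps)),
    nrow = n_haps, ncol = n_snps
  )

  dosage <- matrix(0L, n_ind, n_snps, dimnames = list(ids, map$snp))
  snp_sets <- split(seq_len(n_snps), map$gene)
  for (g in seq_len(n_genes)) {
    s <- snp_sets[[genes$gene[g]]]
    dosage[, s] <- hap_alleles[lab_pat[, g], s, drop = FALSE] +
      hap_alleles[lab_mat[, g], s, drop = FALSE]
  }

  structure(list(
    labels_pat = lab_pat, labels_mat = lab_mat, dosage = dosage,
    founder_haps = tibble(
      label = seq_len(n_haps),
      id = rep(ids[founders], each = 2L),
      haplotype = rep(1:2, length(founders))
    ),
    genes = genes, snps = map$snp, ids = ids
  ), class = "gene_drop")
}

# one meiosis: recombine the parent's two label vectors at the gene loci
meiosis_labels <- function(par_pat, par_mat, pos_cM, gene_sets, chr_len) {
  out <- integer(length(par_pat))
  for (chr in names(gene_sets)) {
    g <- gene_sets[[chr]]
    L <- chr_len[[chr]]
    start <- sample.int(2L, 1L)
    k <- rpois(1L, L / 100)
    if (k == 0L) {
      hap <- rep(start, length(g))
    } else {
      xo <- sort(runif(k, 0, L))
      hap <- 1L + (start - 1L + findInterval(pos_cM[g], xo)) %% 2L
    }
    out[g] <- ifelse(hap == 1L, par_pat[g], par_mat[g])
  }
  out
}

#' @export
print.gene_drop <- function(x, ...) {
  cat(sprintf("<gene_drop> %d individuals, %d genes, %d SNPs, %d founder haplotypes\n",
              length(x$ids), nrow(x$genes), length(x$snps), nrow(x$founder_haps)))
  invisible(x)
}
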