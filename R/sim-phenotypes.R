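#' Simulate replicate phenotypes under a liability-threshold model
#'
#' Plants `n_causal_genes` causal genes; the risk alleles of a causal gene
#' are its rare nonsynonymous SNPs (population `maf < causal_maf_max`),
#' each with liability-scale effect `causal_effect` per minor allele.
#' Causal genes are drawn among genes in which such an allele is carried
#' by at least `causal_min_carriers` individuals — rare alleles enriched
#' by descent from a founder, so affected carriers form the
#' identity-by-descent clusters a family design can detect; when fewer
#' than `n_causal_genes` genes qualify, the carrier requirement is relaxed
#' (with a warning) to any gene carrying a rare nonsynonymous allele.
#' Each replicate draws fresh standard-normal noise on top of the fixed
#' genetic score and declares affected the individuals whose liability
#' exceeds the empirical (1 - prevalence) quantile, so every replicate has
#' an affected fraction equal to the target. Genotypes are fixed across
#' replicates; only affection status varies — emulating repeated phenotype
#' files over one genotype set.
#'
#' @param drop A [gene_drop()] result supplying the dosage matrix.
#' @param map The variant map the genotypes were generated from.
#' @param config A [sim_config()]; uses `n_causal_genes`, `causal_effect`,
#'   `prevalence`, `n_replicates`.
#' @param seed Optional seed.
#' @return An object of class `replicate_set`: list with
#'   * `affected` — logical matrix (individuals x replicates),
#'   * `truth` — list with `causal_genes` (character) and
#'     `causal_variants` (tibble `snp`, `gene`, `beta`),
#'   * `prevalence`, `ids`.
#'   Use [as_tibble()] (columns `replicate`, `id`, `affected`) for the
#'   long form, or [replicate_phenotype()] for one replicate.
#' @export
sim_phenotypes <- function(drop, map, config, seed = NULL) {
  stopifnot(inherits(drop, "gene_drop"))
  validate_sim_config(config)
  maybe_with_seed(seed, sim_phenotypes_impl(drop, map, config))
}

sim_phenotypes_impl <- function(drop, map, config) {
  n_ind <- length(drop$ids)
  rare_ns <- map[map$func == "nonsynonymous" &
                   map$maf < config$causal_maf_max, ]
  if (config$n_causal_genes > 0 && nrow(rare_ns) == 0) {
    abort("no gene carries a rare nonsynonymous SNP; cannot plant causal genes")
  }
  carriers <- colSums(drop$dosage[, rare_ns$snp, drop = FALSE] > 0)
  eligible <- unique(rare_ns$gene[carriers >= config$causal_min_carriers])
  if (config$n_causal_genes > 0 && length(eligible) < config$n_causal_genes) {
    warn(paste0("only ", length(eligible), " gene(s) carry a segregating ",
                "rare risk allele (>= ", config$causal_min_carriers,
                " carriers); relaxing the carrier requirement"))
    eligible <- unique(rare_ns$gene)
  }
  causal_genes <- sort(sample(eligible,
                              min(config$n_causal_genes, length(eligible))))
  cv <- rare_ns[rare_ns$gene %in% causal_genes, c("snp", "gene")]
  cv$beta <- rep(config$causal_effect, nrow(cv))

  genetic <- if (nrow(cv) > 0) {
    as.vector(drop$dosage[, cv$snp, drop = FALSE] %*% cv$beta)
  } else {
    rep(0, n_ind)
  }
  if (nrow(cv) > 0 && all(drop$dosage[, cv$snp] == 0)) {
    warn("no individual carries any causal allele; power will be nil")
  }

  affected <- matrix(FALSE, n_ind, config$n_replicates,
                     dimnames = list(drop$ids,
                                     sprintf("R%03d", seq_len(config$n_replicates))))
  for (r in seq_len(config$n_replicates)) {
    liability <- genetic + rnorm(n_ind)
    affected[, r] <- liability > quantile(liability, 1 - config$prevalence)
  }

  structure(list(
    affected = affected,
    truth = list(causal_genes = causal_genes, causal_variants = cv),
    prevalence = config$prevalence, ids = drop$ids
  ), class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d individuals x %d replicates; prevalence %.2f; %d causal genes\n",
              nrow(x$affected), ncol(x$affected), x$prevalence,
              length(x$truth$causal_genes)))
  invisible(x)
}

#' @export
as_tibble.replicate_set <- function(x, ...) {
  tibble(
    replicate = rep(colnames(x$affected), each = nrow(x$affected)),
    id = rep(x$ids, times = ncol(x$affected)),
    affected = as.vector(x$affected)
  )
}

#' Affection status of one replicate
#'
#' @param phenotypes A `replicate_set` from [sim_phenotypes()].
#' @param replicate Replicate name (e.g. `"R001"`) or index.
#' @return Tibble `id`, `affected` for that replicate.
#' @export
replicate_phenotype <- function(phenotypes, replicate) {
  stopifnot(inherits(phenotypes, "replicate_set"))
  if (is.numeric(replicate)) replicate <- colnames(phenotypes$affected)[replicate]
  if (!replicate %in% colnames(phenotypes$affected)) {
    abort(paste0("unknown replicate: ", replicate))
  }
  tibble(id = phenotypes$ids,
         affected = unname(phenotypes$affected[, replicate]))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running the whole generator under one seed:
#' pedigrees, variant map, gene-drop genotypes and replicate phenotypes
#' with planted causal genes. The result bundles everything a pipeline run
#' needs.
#'
#' @param config A [sim_config()]; its `seed` (when set) makes the study
#'   fully reproducible.
#' @return An object of class `ibd_study`: list with `config`, `pedigree`,
#'   `map`, `drop`, `phenotypes`.
#' @examples
#' study <- simulate_study(sim_config(n_pedigrees = 2, n_genes = 50,
#'                                    n_snps = 150, n_replicates = 5,
#'                                    seed = 11))
#' study$phenotypes$truth$causal_genes
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  maybe_with_seed(config$seed, {
    pedigree <- sim_pedigrees_impl(config)
    map <- sim_variant_map_impl(config)
    drop <- gene_drop_impl(as_pedigree(pedigree), map, gene_layout(map),
                           config$chromosomes)
    phenotypes <- sim_phenotypes_impl(drop, map, config)
    structure(list(config = config, pedigree = pedigree, map = map,
                   drop = drop, phenotypes = phenotypes),
              class = "ibd_study")
  })
}

#' @export
print.ibd_study <- function(x, ...) {
  cat("<ibd_study>\n")
  print(x$config)
  cat(sprintf("  %d individuals; causal genes: %s\n",
              nrow(x$pedigree),
              paste(x$phenotypes$truth$causal_genes, collapse = ", ")))
  invisible(x)
}
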