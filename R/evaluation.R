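#' Funnel report: counts at every pipeline stage
#'
#' Summarises how the candidate set shrinks through the pipeline: all
#' genes, genes selected in at least one replicate, genes kept by the
#' replicate-count threshold, SNPs in the kept genes, SNPs surviving the
#' MAF filter, SNPs surviving the function filter, and variants flagged
#' by the family-based test. From the SNP restriction onward the counts
#' form a subset chain and are therefore non-increasing.
#'
#' @param result An `ibd_pipeline` object from [run_pipeline()].
#' @return Tibble `stage`, `n`.
#' @export
funnel_report <- function(result) {
  stopifnot(inherits(result, "ibd_pipeline"))
  fl <- attr(result$variants, "funnel")
  tibble(
    stage = c("total_genes", "genes_in_ge1_replicate", "genes_kept",
              "snps_in_kept_genes", "snps_after_maf", "snps_after_function",
              "variants_flagged"),
    n = as.integer(c(
      length(unique(result$study$map$gene)),
      nrow(result$filter$ranking),
      sum(result$filter$ranking$kept),
      fl[["in_genes"]], fl[["after_maf"]], fl[["after_func"]],
      sum(result$screen$summary$flagged)
    ))
  )
}

#' Candidate gene/variant table
#'
#' Joins the flagged variants from the association screen with their IBD
#' replicate counts and map annotation — the final deliverable of a
#' pipeline run.
#'
#' @param screen An `fbat_screen` result.
#' @param ranking Aggregated gene ranking (tibble `gene`,
#'   `n_replicates`, `kept`).
#' @param map The variant map.
#' @return Tibble `gene`, `n_replicates`, `snp`, `maf`, `chrom`,
#'   `pos_bp`, `func`, `min_p`, sorted by gene then position; empty (with
#'   the same columns) when nothing was flagged.
#' @export
candidate_table <- function(screen, ranking, map) {
  stopifnot(inherits(screen, "fbat_screen"))
  flagged <- screen$summary[screen$summary$flagged %in% TRUE, c("snp", "min_p")]
  out <- map[map$snp %in% flagged$snp,
             c("gene", "snp", "maf", "chrom", "pos_bp", "func")] |>
    left_join(flagged, by = "snp") |>
    left_join(ranking[c("gene", "n_replicates")], by = "gene") |>
    select("gene", "n_replicates", "snp", "maf", "chrom", "pos_bp",
           "func", "min_p") |>
    arrange(.data$gene, .data$pos_bp)
  out
}

#' Sensitivity of the pipeline against planted truth
#'
#' Re-runs the IBD + association stages over a grid of strategy settings
#' (scoring mode x minimum informative pedigrees) and scores each cell
#' against the simulation's planted causal genes. Both readings of "true
#' positive" are reported: variant-level (a flagged variant is causal)
#' and gene-level (a flagged variant's gene is causal).
#'
#' @param study An `ibd_study` from [simulate_study()].
#' @param modes Scoring modes to sweep (default both).
#' @param min_pedigrees Informative-pedigree minima to sweep (default
#'   `c(3, 5, 8)`).
#' @param lo,hi,gene_cap,replicate_min,maf_threshold,alpha,empirical_variance
#'   Stage parameters, as in [run_pipeline()].
#' @param ibd Optional precomputed [ibd_matrix] over all within-pedigree
#'   pairs (computed once here otherwise).
#' @return Tibble of class `sensitivity_grid`: `mode`, `min_pedigrees`,
#'   `level` (`"variant"`/`"gene"`), `n_true_positive`, `n_selected`,
#'   `tp_percent` (`NA` when nothing selected), `label` (`"x/y (z%)"`,
#'   or `"-"` for undefined cells).
#' @export
sensitivity_grid <- function(study, modes = c("most", "max"),
                             min_pedigrees = c(3, 5, 8),
                             lo = 0.01, hi = 0.09, gene_cap = 100,
                             replicate_min = NULL, maf_threshold = 0.10,
                             alpha = 0.05, empirical_variance = TRUE,
                             ibd = NULL) {
  stopifnot(inherits(study, "ibd_study"))
  ibd <- ibd %||% true_ibd(study$drop, within_ped_pairs(study$pedigree))
  truth <- study$phenotypes$truth
  rows <- list()
  for (mode in modes) {
    filt <- ibd_filter_replicates(ibd, study$phenotypes, mode = mode,
                                  lo = lo, hi = hi, gene_cap = gene_cap,
                                  replicate_min = replicate_min)
    kept_genes <- filt$ranking$gene[filt$ranking$kept]
    variants <- filter_variants(study$map, kept_genes, maf_threshold)
    snps <- variants$snp[variants$kept]
    for (mp in min_pedigrees) {
      screen <- fbat_screen(study$pedigree, study$drop$dosage,
                            study$phenotypes, snps,
                            min_pedigrees = mp, alpha = alpha,
                            empirical_variance = empirical_variance)
      flagged <- screen$summary[screen$summary$flagged %in% TRUE, ]
      flagged_genes <- unique(study$map$gene[match(flagged$snp, study$map$snp)])
      rows[[length(rows) + 1]] <- tibble(
        mode = mode, min_pedigrees = mp,
        level = c("variant", "gene"),
        n_true_positive = c(
          sum(flagged$snp %in% truth$causal_variants$snp),
          sum(flagged_genes %in% truth$causal_genes)
        ),
        n_selected = c(nrow(flagged), length(flagged_genes))
      )
    }
  }
  out <- bind_rows(rows) |>
    mutate(
      tp_percent = ifelse(.data$n_selected > 0,
                          100 * .data$n_true_positive / .data$n_selected,
                          NA_real_),
      label = ifelse(.data$n_selected > 0,
                     sprintf("%d/%d (%.1f)", .data$n_true_positive,
                             .data$n_selected, .data$tp_percent),
                     "-")
    )
  class(out) <- c("sensitivity_grid", class(out))
  out
}
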