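#' Run the full IBD-filtering pipeline
#'
#' Executes the whole strategy end to end on a synthetic study:
#' 1. simulate pedigrees, genotypes, true IBD and replicate phenotypes
#'    ([simulate_study()]);
#' 2. per replicate, select case-case pairs sharing 1%-9% of the genome
#'    and score genes by the number of case subjects sharing them
#'    ([select_pairs()], [gene_share_counts()]);
#' 3. pick each replicate's gene list ("most" or "max" cases) and rank
#'    genes by the number of replicates selecting them
#'    ([ibd_filter_replicates()]);
#' 4. filter the kept genes' variants by population MAF and predicted
#'    function ([filter_variants()]);
#' 5. screen the survivors with the family-based score test and flag
#'    variants by minimum p across replicates ([fbat_screen()]);
#' 6. assemble funnel counts and the candidate table.
#'
#' @param config A [sim_config()] (set its `seed` for reproducibility),
#'   or a ready-made `ibd_study`.
#' @param mode `"most"` or `"max"` cases gene scoring.
#' @param lo,hi Realized-sharing band for pair selection.
#' @param gene_cap Gene-list cap for "most cases" scoring.
#' @param replicate_min Minimum replicate count for a gene to be kept
#'   (default a quarter of the replicates).
#' @param maf_threshold MAF cutoff (strict `<`).
#' @param min_pedigrees Minimum informative pedigrees for the association
#'   screen.
#' @param alpha Cutoff on the minimum association p-value.
#' @param empirical_variance Use the empirical variance in the score test.
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written as TSV via [write_pipeline()].
#' @return An object of class `ibd_pipeline`: list with `study`, `ibd`,
#'   `filter`, `variants`, `screen`, `candidates`, `funnel`, `params`.
#'   [tidy()] returns the candidate table, [glance()] the funnel as one
#'   wide row.
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(n_pedigrees = 2, n_genes = 100,
#'                                n_snps = 400, n_replicates = 8,
#'                                seed = 1))
#' glance(res)
#' }
#' @export
run_pipeline <- function(config, mode = c("most", "max"),
                         lo = 0.01, hi = 0.09, gene_cap = 100,
                         replicate_min = NULL, maf_threshold = 0.10,
                         min_pedigrees = 3, alpha = 0.05,
                         empirical_variance = TRUE, out_dir = NULL) {
  mode <- match.arg(mode)
  study <- if (inherits(config, "ibd_study")) config else simulate_study(config)
  ibd <- true_ibd(study$drop, within_ped_pairs(study$pedigree))
  filt <- ibd_filter_replicates(ibd, study$phenotypes, mode = mode,
                                lo = lo, hi = hi, gene_cap = gene_cap,
                                replicate_min = replicate_min)
  kept_genes <- filt$ranking$gene[filt$ranking$kept]
  variants <- filter_variants(study$map, kept_genes, maf_threshold)
  screen <- fbat_screen(study$pedigree, study$drop$dosage, study$phenotypes,
                        variants$snp[variants$kept],
                        min_pedigrees = min_pedigrees, alpha = alpha,
                        empirical_variance = empirical_variance)
  result <- structure(list(
    study = study, ibd = ibd, filter = filt, variants = variants,
    screen = screen,
    params = list(mode = mode, lo = lo, hi = hi, gene_cap = gene_cap,
                  replicate_min = filt$params$replicate_min,
                  maf_threshold = maf_threshold,
                  min_pedigrees = min_pedigrees, alpha = alpha,
                  empirical_variance = empirical_variance)
  ), class = "ibd_pipeline")
  result$candidates <- candidate_table(screen, filt$ranking, study$map)
  result$funnel <- funnel_report(result)
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.ibd_pipeline <- function(x, ...) {
  cat("<ibd_pipeline>\n")
  f <- x$funnel
  cat(paste0("  ", format(f$stage, width = 24), f$n, collapse = "\n"), "\n")
  if (nrow(x$candidates) > 0) {
    cat(sprintf("  candidate genes: %s\n",
                paste(unique(x$candidates$gene), collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.ibd_pipeline <- function(x, ...) x$candidates

#' @export
glance.ibd_pipeline <- function(x, ...) {
  wide <- setNames(as.list(x$funnel$n), x$funnel$stage)
  as_tibble(c(wide, list(mode = x$params$mode,
                         n_replicates = x$filter$params$n_replicates)))
}
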