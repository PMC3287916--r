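small_run <- function(seed = 101, mode = "most") {
  cfg <- sim_config(n_pedigrees = 2, n_genes = 120, n_snps = 500,
                    n_replicates = 8, causal_effect = 3,
                    causal_min_carriers = 5, seed = seed)
  run_pipeline(cfg, mode = mode, min_pedigrees = 2)
}

test_that("funnel counts equal an independent recount of stage outputs", {
  res <- small_run()
  f <- stats::setNames(res$funnel$n, res$funnel$stage)
  study <- res$study
  kept <- res$filter$ranking$gene[res$filter$ranking$kept]
  expect_equal(f[["total_genes"]], dplyr::n_distinct(study$map$gene))
  expect_equal(f[["genes_in_ge1_replicate"]],
               dplyr::n_distinct(res$filter$genes$gene))
  expect_equal(f[["genes_kept"]], length(kept))
  expect_equal(f[["snps_in_kept_genes"]], sum(study$map$gene %in% kept))
  expect_equal(f[["snps_after_maf"]],
               sum(study$map$gene %in% kept & study$map$maf < 0.1))
  expect_equal(f[["snps_after_function"]],
               sum(study$map$gene %in% kept & study$map$maf < 0.1 &
                     study$map$func == "nonsynonymous"))
  expect_equal(f[["variants_flagged"]], sum(res$screen$summary$flagged))
  # subset chain is non-increasing from the SNP restriction onward
  chain <- f[c("snps_in_kept_genes", "snps_after_maf", "snps_after_function",
               "variants_flagged")]
  expect_true(all(diff(unname(chain)) <= 0))
})

test_that("candidate table joins flagged variants with their provenance", {
  res <- small_run()
  cand <- tidy(res)
  expect_named(cand, c("gene", "n_replicates", "snp", "maf", "chrom",
                       "pos_bp", "func", "min_p"))
  if (nrow(cand) > 0) {
    expect_true(all(cand$gene %in%
                      res$filter$ranking$gene[res$filter$ranking$kept]))
    expect_true(all(cand$min_p < res$params$alpha))
    expect_true(all(cand$func == "nonsynonymous"))
    expect_true(all(cand$maf < 0.1))
    # cross-check each row against the stage outputs it came from
    for (i in seq_len(nrow(cand))) {
      expect_equal(cand$min_p[i],
                   res$screen$summary$min_p[res$screen$summary$snp == cand$snp[i]])
      expect_equal(cand$n_replicates[i],
                   res$filter$ranking$n_replicates[
                     res$filter$ranking$gene == cand$gene[i]])
    }
  }
})

test_that("sensitivity grid reports both TP readings with sane cells", {
  cfg <- sim_config(n_pedigrees = 2, n_genes = 120, n_snps = 500,
                    n_replicates = 8, causal_effect = 3,
                    causal_min_carriers = 5, seed = 19)
  study <- simulate_study(cfg)
  grid <- sensitivity_grid(study, min_pedigrees = c(1, 2))
  expect_setequal(unique(grid$level), c("variant", "gene"))
  expect_true(all(grid$n_true_positive <= grid$n_selected))
  defined <- !is.na(grid$tp_percent)
  expect_equal(grid$tp_percent[defined],
               100 * grid$n_true_positive[defined] / grid$n_selected[defined])
  expect_true(all(grid$label[!defined] == "-"))

  # candidate counts shrink as the informativeness minimum rises,
  # and "max" never selects more than "most" at equal settings
  wide <- grid[grid$level == "variant", ]
  for (m in unique(wide$mode)) {
    sub <- wide[wide$mode == m, ]
    sub <- sub[order(sub$min_pedigrees), ]
    expect_true(all(diff(sub$n_selected) <= 0))
  }
  for (mp in unique(wide$min_pedigrees)) {
    sub <- wide[wide$min_pedigrees == mp, ]
    expect_true(sub$n_selected[sub$mode == "max"] <=
                  sub$n_selected[sub$mode == "most"])
  }
})

test_that("a truth set covering all candidates gives 100% sensitivity", {
  res <- small_run(seed = 103)
  study <- res$study
  flagged <- res$screen$summary$snp[res$screen$summary$flagged]
  expect_gt(length(flagged), 0)   # this seed flags at least one variant
  study$phenotypes$truth$causal_variants <-
    tibble::tibble(snp = flagged,
                   gene = study$map$gene[match(flagged, study$map$snp)],
                   beta = 1)
  study$phenotypes$truth$causal_genes <-
    unique(study$phenotypes$truth$causal_variants$gene)
  grid <- sensitivity_grid(study, modes = res$params$mode, min_pedigrees = 2)
  cell <- grid[grid$level == "variant", ]
  expect_equal(cell$tp_percent, 100)
})
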