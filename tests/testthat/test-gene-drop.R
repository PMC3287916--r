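test_that("every transmitted label traces to a founder and parents share one", {
  cfg <- sim_config(n_pedigrees = 1, n_genes = 25, n_snps = 50, seed = 9)
  ped <- sim_pedigrees(cfg)
  map <- sim_variant_map(cfg)
  drop <- gene_drop(ped, map, cfg$chromosomes, seed = 9)

  founder_labs <- drop$founder_haps$label
  expect_true(all(drop$labels_pat %in% founder_labs))
  expect_true(all(drop$labels_mat %in% founder_labs))

  # founders carry their own two unique labels at every gene
  f_ids <- ped$id[ped$founder]
  expect_true(all(apply(drop$labels_pat[f_ids, , drop = FALSE], 1,
                        function(x) length(unique(x)) == 1)))
  # offspring share exactly one label with each parent at every gene
  kids <- ped[!ped$founder, ]
  for (i in seq_len(min(10, nrow(kids)))) {
    kid <- kids$id[i]
    k_lab <- rbind(drop$labels_pat[kid, ], drop$labels_mat[kid, ])
    for (par in c(kids$father[i], kids$mother[i])) {
      p_lab <- rbind(drop$labels_pat[par, ], drop$labels_mat[par, ])
      shared <- colSums(k_lab == p_lab[c(1, 1), ] | k_lab == p_lab[c(2, 2), ])
      expect_true(all(shared == 1),
                  label = paste("one shared label with", par))
    }
  }
})

test_that("a 0 cM chromosome transmits whole parental haplotypes", {
  chrom <- tibble::tibble(chrom = "1", length_cM = 0)
  cfg <- sim_config(n_pedigrees = 1, depth = 3, n_genes = 20, n_snps = 20,
                    chromosomes = chrom, seed = 3)
  ped <- sim_pedigrees(cfg)
  map <- sim_variant_map(cfg)
  drop <- gene_drop(ped, map, chrom, seed = 3)
  for (kid in ped$id[!ped$founder]) {
    for (m in c("labels_pat", "labels_mat")) {
      expect_equal(length(unique(drop[[m]][kid, ])), 1,
                   label = paste(kid, m, "constant along 0 cM chromosome"))
    }
  }
})

test_that("mean IBD of simulated first-cousin pairs matches (1/2)^3", {
  # one founder couple, two married children, one grandchild each;
  # a single unlinked locus per drop
  cous <- tibble::tibble(
    ped = "1",
    id = c("g1", "g2", "a", "b", "sa", "sb", "x", "y"),
    father = c(NA, NA, "g1", "g1", NA, NA, "a", "b"),
    mother = c(NA, NA, "g2", "g2", NA, NA, "sa", "sb"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 2)
  )
  chrom <- tibble::tibble(chrom = "1", length_cM = 0)
  map <- tibble::tibble(snp = "s1", chrom = "1", pos_bp = 1, pos_cM = 0,
                        gene = "g1", maf = 0.1, func = "synonymous")
  n_rep <- 1500
  withr::with_seed(123, {
    scores <- vapply(seq_len(n_rep), function(i) {
      d <- gene_drop(cous, map, chrom)
      true_ibd(d, tibble::tibble(id1 = "x", id2 = "y"))$score[1, 1]
    }, numeric(1))
  })
  se <- stats::sd(scores) / sqrt(n_rep)
  expect_lt(abs(mean(scores) - 0.125), 3 * se)
})

test_that("IBD scores encode the shared-allele count", {
  labs_pat <- rbind(a = c(1L, 1L, 1L, 1L), b = c(1L, 3L, 1L, 5L))
  labs_mat <- rbind(a = c(2L, 2L, 2L, 2L), b = c(2L, 4L, 4L, 6L))
  drop <- structure(list(
    labels_pat = labs_pat, labels_mat = labs_mat,
    genes = tibble::tibble(gene = paste0("g", 1:4), chrom = "1",
                           pos_cM = 1:4),
    ids = c("a", "b")
  ), class = "gene_drop")
  colnames(drop$labels_pat) <- colnames(drop$labels_mat) <- drop$genes$gene
  ibd <- true_ibd(drop, tibble::tibble(id1 = "a", id2 = "b"))
  # both shared / none / one via mat / none
  expect_equal(unname(ibd$score[1, ]), c(1, 0, 0.5, 0))
  expect_error(true_ibd(drop, tibble::tibble(id1 = "a", id2 = "zz")),
               "unknown")
})

test_that("score 1 never occurs outside full-sib or self-like pairs", {
  cfg <- sim_config(n_pedigrees = 1, n_genes = 120, n_snps = 240,
                    n_causal_genes = 0, seed = 31)
  study <- simulate_study(cfg)
  ped <- study$pedigree
  pairs <- within_ped_pairs(ped)
  ibd <- true_ibd(study$drop, pairs)
  sibkey <- paste(ped$father, ped$mother)
  sib_of <- stats::setNames(sibkey, ped$id)
  full_sibs <- !ped$founder[match(pairs$id1, ped$id)] &
    !ped$founder[match(pairs$id2, ped$id)] &
    sib_of[pairs$id1] == sib_of[pairs$id2]
  expect_true(all(ibd$score[!full_sibs, ] < 1))
  expect_true(all(ibd$score %in% c(0, 0.5, 1)))
})
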