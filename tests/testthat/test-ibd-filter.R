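# Small hand-built IBD fixture over cases A..E and genes g1..g4.
toy_ibd <- function() {
  pairs <- tibble::tibble(
    id1 = c("A", "B", "A", "A"),
    id2 = c("B", "C", "C", "D")
  )
  score <- rbind(
    c(0.5, 0,   0.5, 0),    # A-B
    c(0.5, 0.5, 0,   0),    # B-C
    c(0,   0.5, 0,   0),    # A-C
    c(0,   0,   0,   0)     # A-D
  )
  colnames(score) <- paste0("g", 1:4)
  ibdfilter:::new_ibd_matrix(score, pairs)
}

test_that("pair selection honours the sharing band and case status", {
  score <- matrix(c(0.12, 0.05, 0.05, 0.009, 0.09, 0.01),
                  ncol = 1, dimnames = list(NULL, "g1"))
  score <- score[, rep(1, 100)]   # 100 genes so rowMeans equal the value
  colnames(score) <- paste0("g", 1:100)
  pairs <- tibble::tibble(id1 = c("a", "b", "c", "d", "e", "f"),
                          id2 = c("p", "q", "r", "s", "t", "u"))
  ibd <- ibdfilter:::new_ibd_matrix(score, pairs)
  pheno <- tibble::tibble(
    id = c(pairs$id1, pairs$id2),
    affected = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  sel <- select_pairs(ibd, pheno)
  # 0.12 out of band; 0.05 kept; 0.05 with unaffected partner dropped;
  # 0.009 below; 0.09 and 0.01 are inclusive bounds
  expect_setequal(sel$id1, c("b", "e", "f"))
  expect_setequal(attr(sel, "cases"), c("b", "q", "e", "t", "f", "u"))

  none <- tibble::tibble(id = pheno$id, affected = FALSE)
  expect_warning(out <- select_pairs(ibd, none), "no case-case pair")
  expect_equal(nrow(out), 0)
})

test_that("gene case counts are unions of subjects over supporting pairs", {
  ibd <- toy_ibd()
  sel <- tibble::tibble(id1 = c("A", "B", "A", "A"),
                        id2 = c("B", "C", "C", "D"), sharing = 0.05)
  counts <- gene_share_counts(ibd, sel)
  # g1: pairs (A,B),(B,C) -> {A,B,C}; g2: (B,C),(A,C) -> {A,B,C};
  # g3: (A,B) -> {A,B}; g4: nobody -> excluded
  expect_equal(counts$n_cases[counts$gene == "g1"], 3L)
  expect_equal(counts$n_cases[counts$gene == "g2"], 3L)
  expect_equal(counts$n_cases[counts$gene == "g3"], 2L)
  expect_false("g4" %in% counts$gene)
})

test_that("case counts match a brute-force union oracle on random fixtures", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      n_pairs <- 12; n_genes <- 8
      ids <- LETTERS[1:7]
      all_pairs <- t(utils::combn(ids, 2))
      pick <- all_pairs[sample(nrow(all_pairs), n_pairs), , drop = FALSE]
      pairs <- tibble::tibble(id1 = pick[, 1], id2 = pick[, 2])
      score <- matrix(sample(c(0, 0.5), n_pairs * n_genes, TRUE, c(0.7, 0.3)),
                      n_pairs, n_genes,
                      dimnames = list(NULL, paste0("g", 1:n_genes)))
      ibd <- ibdfilter:::new_ibd_matrix(score, pairs)
      sel <- tibble::tibble(pairs, sharing = 0.05)
      counts <- gene_share_counts(ibd, sel)
      for (g in colnames(score)) {
        supp <- score[, g] > 0
        brute <- length(unique(c(pairs$id1[supp], pairs$id2[supp])))
        got <- counts$n_cases[counts$gene == g]
        expect_equal(if (length(got)) got else 0L, as.integer(brute))
      }
    }
  })
})

test_that("most-cases walks thresholds down to the cap", {
  counts <- tibble::tibble(gene = LETTERS[1:5], n_cases = c(6L, 5L, 5L, 3L, 2L))
  out <- most_cases_genes(counts, gene_cap = 3)
  expect_equal(attr(out, "threshold_k"), 6)
  expect_equal(out$gene, "A")

  single <- tibble::tibble(gene = "Z", n_cases = 2L)
  out2 <- most_cases_genes(single, gene_cap = 100)
  expect_equal(attr(out2, "threshold_k"), 2)
  expect_equal(out2$gene, "Z")

  # cap unreachable: every threshold holds >= cap genes or none
  flat <- tibble::tibble(gene = paste0("G", 1:5), n_cases = rep(4L, 5))
  expect_error(most_cases_genes(flat, gene_cap = 3), "gene_cap")
  expect_error(most_cases_genes(counts[0, ]), "empty")
})

test_that("max-cases keeps the argmax set including ties", {
  counts <- tibble::tibble(gene = c("A", "B", "C"), n_cases = c(6L, 5L, 6L))
  out <- max_cases_genes(counts)
  expect_setequal(out$gene, c("A", "C"))
  expect_equal(attr(out, "threshold_k"), 6)
  expect_equal(max_cases_genes(tibble::tibble(gene = c("A", "B"),
                                              n_cases = c(6L, 5L)))$gene, "A")
  expect_error(max_cases_genes(counts[0, ]), "empty")
})

test_that("most-cases output always contains the max-cases output", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      counts <- tibble::tibble(
        gene = paste0("G", 1:30),
        n_cases = sample(2:12, 30, replace = TRUE)
      )
      mx <- max_cases_genes(counts)
      mo <- tryCatch(most_cases_genes(counts, gene_cap = 10),
                     error = function(e) NULL)
      if (!is.null(mo)) expect_true(all(mx$gene %in% mo$gene))
      # n_genes(k) is non-increasing in k
      tab <- share_count_table(counts)
      expect_true(all(diff(tab$n_genes) <= 0))
    }
  })
})

test_that("replicate aggregation keeps genes above the threshold", {
  sel <- tibble::tibble(
    replicate = rep(sprintf("R%03d", 1:200), times = 2),
    gene = c(rep("F5x", 200), rep("Gq", 200))
  )[c(1:140, 201:249), ]     # F5x in 140 lists, Gq in 49
  agg <- aggregate_replicates(sel, n_replicates = 200, replicate_min = 50)
  expect_true(agg$kept[agg$gene == "F5x"])
  expect_false(agg$kept[agg$gene == "Gq"])
  expect_equal(agg$n_replicates[agg$gene == "F5x"], 140L)

  one <- aggregate_replicates(tibble::tibble(replicate = "R001", gene = "A"),
                              n_replicates = 1, replicate_min = 1)
  expect_equal(one$gene, "A")
  expect_true(one$kept)
  expect_error(aggregate_replicates(sel, 200, replicate_min = 201),
               "exceeds")
})

test_that("default keep threshold is a quarter of the replicates", {
  sel <- tibble::tibble(replicate = sprintf("R%03d", 1:8), gene = "A")
  agg <- aggregate_replicates(sel, n_replicates = 20)   # min = ceiling(5)
  expect_true(agg$kept)
  agg4 <- aggregate_replicates(sel[1:4, ], n_replicates = 20)
  expect_false(agg4$kept)
})
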