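#' Select distant case-case relative pairs by realized genome sharing
#'
#' The filtering strategy rests on affected pairs of distant relatives:
#' pairs in which both members are affected and whose realized genome
#' sharing (mean per-gene IBD score) falls inside `[lo, hi]`. The default
#' band of 1%-9% captures fourth- and fifth-degree relatives while
#' excluding anything sharing more of the genome.
#'
#' @param ibd An [ibd_matrix] covering the candidate pairs.
#' @param phenotype Tibble (`id`, `affected`) for one replicate, e.g. from
#'   [replicate_phenotype()].
#' @param lo,hi Inclusive bounds on realized sharing (defaults 0.01 and
#'   0.09).
#' @return Tibble `id1`, `id2`, `sharing` of the selected pairs, with the
#'   distinct case ids in attribute `"cases"`. Empty (with a warning) when
#'   no affected pair qualifies.
#' @export
select_pairs <- function(ibd, phenotype, lo = 0.01, hi = 0.09) {
  stopifnot(inherits(ibd, "ibd_matrix"))
  aff <- phenotype$id[phenotype$affected %in% TRUE]
  unknown <- setdiff(c(ibd$pairs$id1, ibd$pairs$id2), phenotype$id)
  if (length(unknown) > 0) {
    abort(paste0("phenotype missing for: ", paste(head(unknown, 5), collapse = ", ")))
  }
  sharing <- unname(rowMeans(ibd$score))
  keep <- ibd$pairs$id1 %in% aff & ibd$pairs$id2 %in% aff &
    sharing >= lo & sharing <= hi
  out <- tibble(id1 = ibd$pairs$id1[keep], id2 = ibd$pairs$id2[keep],
                sharing = sharing[keep])
  if (nrow(out) == 0) warn("no case-case pair falls inside the sharing band")
  attr(out, "cases") <- sort(unique(c(out$id1, out$id2)))
  out
}

#' Count case subjects sharing each gene
#'
#' For every gene, counts the distinct case subjects that appear in at
#' least one selected pair whose IBD score at that gene is greater than 0.
#' A case counts once however many supporting pairs it belongs to. Genes
#' shared by no selected pair are omitted.
#'
#' @param ibd An [ibd_matrix].
#' @param selection Selected pairs from [select_pairs()].
#' @return Tibble `gene`, `n_cases`, sorted by decreasing `n_cases`.
#' @export
gene_share_counts <- function(ibd, selection) {
  stopifnot(inherits(ibd, "ibd_matrix"))
  if (nrow(selection) == 0) {
    return(tibble(gene = character(), n_cases = integer()))
  }
  sub <- ibd_subset(ibd, selection)
  cases <- sort(unique(c(sub$pairs$id1, sub$pairs$id2)))
  # membership: cases x pairs (a pair supports both its members)
  M <- matrix(0L, length(cases), nrow(sub$pairs))
  M[cbind(match(sub$pairs$id1, cases), seq_len(nrow(sub$pairs)))] <- 1L
  M[cbind(match(sub$pairs$id2, cases), seq_len(nrow(sub$pairs)))] <- 1L
  support <- M %*% (sub$score > 0)        # cases x genes: supporting pairs
  n_cases <- colSums(support > 0)
  keep <- n_cases > 0
  tibble(gene = colnames(sub$score)[keep],
         n_cases = as.integer(n_cases[keep])) |>
    arrange(dplyr::desc(.data$n_cases), .data$gene)
}

#' Per-threshold summary of gene sharing (funnel table)
#'
#' For each sharing threshold k, reports how many genes are shared by at
#' least k case subjects and how many SNPs (total, rare, synonymous,
#' nonsynonymous) those genes contain — the per-replicate funnel view of
#' the filtering stage.
#'
#' @param counts Output of [gene_share_counts()].
#' @param map Optional variant map; when given, SNP totals are added.
#' @param maf_threshold MAF cutoff defining "rare" (default 0.1, strict
#'   `<`).
#' @return Tibble `k`, `n_genes` (+ `total_snps`, `rare_snps`,
#'   `synonymous`, `nonsynonymous` when `map` is given), for k from 2 to
#'   the maximum observed count.
#' @export
share_count_table <- function(counts, map = NULL, maf_threshold = 0.1) {
  if (nrow(counts) == 0) {
    return(tibble(k = integer(), n_genes = integer()))
  }
  ks <- 2:max(counts$n_cases)
  out <- tibble(
    k = ks,
    n_genes = vapply(ks, function(k) sum(counts$n_cases >= k), integer(1))
  )
  if (!is.null(map)) {
    per_k <- lapply(ks, function(k) counts$gene[counts$n_cases >= k])
    snp_stats <- function(genes) {
      m <- map[map$gene %in% genes, ]
      c(total_snps = nrow(m),
        rare_snps = sum(m$maf < maf_threshold),
        synonymous = sum(m$func == "synonymous"),
        nonsynonymous = sum(m$func == "nonsynonymous"))
    }
    stats <- t(vapply(per_k, snp_stats, numeric(4)))
    out <- dplyr::bind_cols(out, as_tibble(stats))
  }
  out
}

#' Select a replicate's gene list by "most cases" scoring
#'
#' Walks down the sharing thresholds and stops at the smallest k (>= 2)
#' for which fewer than `gene_cap` genes are shared by at least k case
#' subjects; all those genes form the replicate's list. The cap keeps the
#' list from ballooning under locus heterogeneity while avoiding a
#' single-gene commitment.
#'
#' @param counts Output of [gene_share_counts()].
#' @param gene_cap Upper bound on the list size (default 100).
#' @return Tibble `gene`, `n_cases` of the selected genes, with attributes
#'   `threshold_k` and `mode = "most"`.
#' @export
most_cases_genes <- function(counts, gene_cap = 100) {
  if (nrow(counts) == 0) abort("empty gene-share table")
  tab <- share_count_table(counts)
  ok <- tab$n_genes > 0 & tab$n_genes < gene_cap
  if (!any(ok)) {
    abort(sprintf(paste0(
      "no sharing threshold yields a gene list below the cap: ",
      "n_genes ranges %d..%d over k = 2..%d with gene_cap = %d"),
      min(tab$n_genes), max(tab$n_genes), max(tab$k), gene_cap))
  }
  k <- tab$k[which(ok)[1]]
  out <- counts[counts$n_cases >= k, ]
  structure(out, threshold_k = k, mode = "most")
}

#' Select a replicate's gene list by "max cases" scoring
#'
#' Keeps only the gene or genes shared identical by descent by the
#' maximum number of case subjects; ties are all retained.
#'
#' @param counts Output of [gene_share_counts()].
#' @return Tibble `gene`, `n_cases` (the argmax set), with attributes
#'   `threshold_k` (the maximum) and `mode = "max"`.
#' @export
max_cases_genes <- function(counts) {
  if (nrow(counts) == 0) abort("empty gene-share table")
  k <- max(counts$n_cases)
  structure(counts[counts$n_cases == k, ], threshold_k = k, mode = "max")
}

#' Aggregate per-replicate gene lists into a replicate-count ranking
#'
#' Ranks each gene by the number of phenotype replicates in which it was
#' selected, keeping genes selected in at least `replicate_min` replicates
#' (default: a quarter of them, e.g. 50 of 200).
#'
#' @param selections Long tibble with columns `replicate` and `gene` (one
#'   row per gene per replicate list), e.g. the `genes` element of
#'   [ibd_filter_replicates()].
#' @param n_replicates Total number of replicates run.
#' @param replicate_min Minimum replicate count to keep a gene; default
#'   `ceiling(0.25 * n_replicates)`.
#' @return Tibble `gene`, `n_replicates`, `kept`, sorted by decreasing
#'   count.
#' @export
aggregate_replicates <- function(selections, n_replicates,
                                 replicate_min = NULL) {
  replicate_min <- replicate_min %||% ceiling(0.25 * n_replicates)
  if (replicate_min > n_replicates) {
    abort("replicate_min exceeds the number of replicates")
  }
  selections |>
    distinct(.data$replicate, .data$gene) |>
    count(.data$gene, name = "n_replicates") |>
    mutate(kept = .data$n_replicates >= replicate_min) |>
    arrange(dplyr::desc(.data$n_replicates), .data$gene)
}

#' Run the IBD filtering stage over all phenotype replicates
#'
#' For each replicate: select distant case-case pairs, count case sharing
#' per gene, and extract the replicate's gene list under the requested
#' scoring mode; then aggregate lists across replicates into the final
#' replicate-count ranking.
#'
#' @param ibd An [ibd_matrix] covering all within-pedigree pairs that
#'   could become case-case pairs.
#' @param phenotypes A `replicate_set` (or long tibble `replicate`, `id`,
#'   `affected`).
#' @param mode `"most"` or `"max"` cases scoring.
#' @param lo,hi Sharing band passed to [select_pairs()].
#' @param gene_cap Cap for `"most"` scoring.
#' @param replicate_min Passed to [aggregate_replicates()].
#' @return An object of class `ibd_filter`: list with
#'   * `genes` — long tibble `replicate`, `mode`, `k`, `gene`,
#'   * `ranking` — the aggregated ranking with `kept` flags,
#'   * `pair_summary` — per replicate: pairs selected, distinct cases,
#'   * `params`.
#' @export
ibd_filter_replicates <- function(ibd, phenotypes, mode = c("most", "max"),
                                  lo = 0.01, hi = 0.09, gene_cap = 100,
                                  replicate_min = NULL) {
  mode <- match.arg(mode)
  pheno_long <- if (inherits(phenotypes, "replicate_set")) {
    as_tibble(phenotypes)
  } else {
    as_tibble(phenotypes)
  }
  reps <- unique(pheno_long$replicate)
  gene_rows <- list()
  pair_rows <- list()
  for (r in reps) {
    ph <- pheno_long[pheno_long$replicate == r, c("id", "affected")]
    sel <- withCallingHandlers(
      select_pairs(ibd, ph, lo = lo, hi = hi),
      warning = function(w) invokeRestart("muffleWarning")
    )
    pair_rows[[r]] <- tibble(replicate = r, n_pairs = nrow(sel),
                             n_cases = length(attr(sel, "cases")))
    if (nrow(sel) == 0) next
    counts <- gene_share_counts(ibd, sel)
    if (nrow(counts) == 0) next
    picked <- if (mode == "most") {
      tryCatch(most_cases_genes(counts, gene_cap), error = function(e) NULL)
    } else {
      max_cases_genes(counts)
    }
    if (is.null(picked)) next
    gene_rows[[r]] <- tibble(replicate = r, mode = mode,
                             k = attr(picked, "threshold_k"),
                             gene = picked$gene)
  }
  genes <- bind_rows(gene_rows)
  if (nrow(genes) == 0) {
    genes <- tibble(replicate = character(), mode = character(),
                    k = integer(), gene = character())
  }
  ranking <- if (nrow(genes) > 0) {
    aggregate_replicates(genes, length(reps), replicate_min)
  } else {
    tibble(gene = character(), n_replicates = integer(), kept = logical())
  }
  structure(list(
    genes = genes, ranking = ranking, pair_summary = bind_rows(pair_rows),
    params = list(mode = mode, lo = lo, hi = hi, gene_cap = gene_cap,
                  replicate_min = replicate_min %||%
                    ceiling(0.25 * length(reps)),
                  n_replicates = length(reps))
  ), class = "ibd_filter")
}

#' @export
print.ibd_filter <- function(x, ...) {
  cat(sprintf("<ibd_filter> mode '%s': %d replicates, %d genes selected at least once, %d kept (>= %d replicates)\n",
              x$params$mode, x$params$n_replicates, nrow(x$ranking),
              sum(x$ranking$kept), x$params$replicate_min))
  invisible(x)
}

#' @export
tidy.ibd_filter <- function(x, ...) x$ranking

#' @export
glance.ibd_filter <- function(x, ...) {
  tibble(
    mode = x$params$mode,
    n_replicates = x$params$n_replicates,
    replicate_min = x$params$replicate_min,
    n_genes_selected = nrow(x$ranking),
    n_genes_kept = sum(x$ranking$kept),
    mean_pairs = mean(x$pair_summary$n_pairs)
  )
}
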