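#' Per-gene IBD score matrices
#'
#' An `ibd_matrix` stores, for a set of individual pairs and a set of
#' genes, the identity-by-descent score of each pair at each gene: 0 (no
#' allele shared), 0.5 (one allele shared) or 1 (both alleles shared —
#' which in outbred pedigrees only full siblings or twins can attain).
#'
#' `true_ibd()` computes these scores exactly from a gene-drop genome: at
#' each gene the score is half the size of the maximum matching between
#' the two individuals' founder-label pairs.
#'
#' @param drop A [gene_drop()] result.
#' @param pairs Tibble (`id1`, `id2`) of pairs to score. Defaults to all
#'   within-pedigree pairs of `pedigree` when supplied via
#'   [within_ped_pairs()].
#' @return An object of class `ibd_matrix`: list with `score` (pairs x
#'   genes matrix), `pairs` (tibble `id1`, `id2`), `genes`.
#' @examples
#' cfg <- sim_config(n_pedigrees = 1, n_genes = 30, n_snps = 60, seed = 5)
#' ped <- sim_pedigrees(cfg)
#' drop <- gene_drop(ped, sim_variant_map(cfg), cfg$chromosomes, seed = 5)
#' ibd <- true_ibd(drop, within_ped_pairs(ped)[1:5, ])
#' realized_sharing(ibd)
#' @export
true_ibd <- function(drop, pairs) {
  stopifnot(inherits(drop, "gene_drop"))
  pairs <- as_tibble(pairs)[c("id1", "id2")]
  unknown <- setdiff(c(pairs$id1, pairs$id2), drop$ids)
  if (length(unknown) > 0) {
    abort(paste0("unknown individual id(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  i1 <- match(pairs$id1, drop$ids)
  i2 <- match(pairs$id2, drop$ids)
  a1 <- drop$labels_pat[i1, , drop = FALSE]
  a2 <- drop$labels_mat[i1, , drop = FALSE]
  b1 <- drop$labels_pat[i2, , drop = FALSE]
  b2 <- drop$labels_mat[i2, , drop = FALSE]
  # outbred individuals carry two distinct labels, so the maximum matching
  # size is the number of i-labels present among j's labels, capped at 2
  m <- (a1 == b1 | a1 == b2) + (a2 == b1 | a2 == b2)
  score <- 0.5 * pmin(m, 2L)
  dimnames(score) <- list(pair_key(pairs$id1, pairs$id2), drop$genes$gene)
  new_ibd_matrix(score, pairs)
}

new_ibd_matrix <- function(score, pairs) {
  structure(list(score = score, pairs = as_tibble(pairs),
                 genes = colnames(score)),
            class = "ibd_matrix")
}

#' @export
print.ibd_matrix <- function(x, ...) {
  cat(sprintf("<ibd_matrix> %d pairs x %d genes; mean score %.4f\n",
              nrow(x$pairs), length(x$genes), mean(x$score)))
  invisible(x)
}

#' @export
as_tibble.ibd_matrix <- function(x, ...) {
  tibble(
    id1 = rep(x$pairs$id1, times = length(x$genes)),
    id2 = rep(x$pairs$id2, times = length(x$genes)),
    gene = rep(x$genes, each = nrow(x$pairs)),
    score = as.vector(x$score)
  )
}

#' All within-pedigree pairs of individuals
#'
#' @param pedigree A pedigree tibble.
#' @return Tibble `ped`, `id1`, `id2`, one row per unordered pair of
#'   members of the same pedigree.
#' @export
within_ped_pairs <- function(pedigree) {
  pedigree <- as_pedigree(pedigree)
  purrr::map_dfr(split(pedigree$id, pedigree$ped), function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    tibble(id1 = cmb[1, ], id2 = cmb[2, ])
  }, .id = "ped")
}

#' Subset an IBD matrix to a set of pairs
#'
#' @param ibd An [ibd_matrix].
#' @param pairs Tibble (`id1`, `id2`); pair order within a row is
#'   irrelevant.
#' @return An `ibd_matrix` restricted to (and ordered as) `pairs`.
#' @export
ibd_subset <- function(ibd, pairs) {
  stopifnot(inherits(ibd, "ibd_matrix"))
  key <- pair_key(pairs$id1, pairs$id2)
  hit <- match(key, pair_key(ibd$pairs$id1, ibd$pairs$id2))
  if (anyNA(hit)) {
    abort(paste0("pair(s) absent from IBD matrix: ",
                 paste(head(key[is.na(hit)], 5), collapse = ", ")))
  }
  new_ibd_matrix(ibd$score[hit, , drop = FALSE], as_tibble(pairs)[c("id1", "id2")])
}
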