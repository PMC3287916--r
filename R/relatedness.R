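#' Kinship coefficients for a pedigree
#'
#' The kinship coefficient phi(i, j) is the probability that one allele
#' drawn at random from i and one from j are identical by descent. It is
#' computed by the standard tabular recursion in topological order:
#' phi(i, i) = (1 + phi(father_i, mother_i)) / 2, and for j processed
#' before i, phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2, with
#' distinct founders unrelated. For a non-inbred pair the expected fraction
#' of the genome shared identical by descent is g = 2 * phi.
#'
#' @param pedigree A pedigree tibble (see [as_pedigree()]).
#' @return `kinship_matrix()` returns a dense symmetric matrix with
#'   dimnames equal to the individual ids (individuals from different
#'   pedigrees have kinship 0).
#' @examples
#' ped <- sim_pedigrees(sim_config(n_pedigrees = 1, seed = 1))
#' K <- kinship_matrix(ped)
#' @export
kinship_matrix <- function(pedigree) {
  pedigree <- as_pedigree(pedigree)   # topological order
  n <- nrow(pedigree)
  ids <- pedigree$id
  idx <- setNames(seq_len(n), ids)
  fa <- idx[pedigree$father]
  mo <- idx[pedigree$mother]
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
      before <- seq_len(i - 1L)
      v <- 0.5 * (K[fa[i], before] + K[mo[i], before])
      K[i, before] <- v
      K[before, i] <- v
    }
  }
  K
}

#' @rdname kinship_matrix
#' @param id1,id2 Individual ids.
#' @return `kinship()` returns a single probability.
#' @export
kinship <- function(pedigree, id1, id2) {
  pedigree <- as_pedigree(pedigree)
  miss <- setdiff(c(id1, id2), pedigree$id)
  if (length(miss) > 0) {
    abort(paste0("unknown individual id(s): ", paste(miss, collapse = ", ")))
  }
  if (pedigree$ped[match(id1, pedigree$id)] !=
      pedigree$ped[match(id2, pedigree$id)]) {
    return(0)
  }
  sub <- pedigree[pedigree$ped == pedigree$ped[match(id1, pedigree$id)], ]
  K <- kinship_matrix(sub)
  unname(K[id1, id2])
}

#' Expected genome fraction shared by relatives of a given degree
#'
#' Relatives of degree m are expected to share (1/2)^m of their genomes
#' identical by descent: 50% for parent-offspring, 25% for second-degree
#' pairs (grandparental, avuncular), 12.5% for first cousins, 6.25% for
#' fourth-degree and about 3.13% for fifth-degree relatives. Realized
#' sharing varies around this expectation through recombination, the more
#' so the more distant the pair.
#'
#' @param degree Integer vector of relationship degrees (>= 1).
#' @return Numeric vector of expected genome fractions, `(1/2)^degree`.
#' @examples
#' expected_sharing(1:5)
#' @export
expected_sharing <- function(degree) {
  if (length(degree) == 0) return(numeric(0))
  if (any(is.na(degree)) || any(degree < 1) || any(degree != round(degree))) {
    abort("degree must be a positive integer (>= 1)")
  }
  0.5^degree
}

# Map a kinship coefficient to a relationship degree: g = 2*phi and
# degree = -log2(g), rounded; `exact` flags whether 2*phi is a power of 1/2.
degree_from_kinship <- function(phi, tol = 1e-9) {
  degree <- rep(NA_integer_, length(phi))
  exact <- rep(NA, length(phi))
  pos <- !is.na(phi) & phi > 0
  lg <- -log2(2 * phi[pos])
  degree[pos] <- as.integer(pmax(1L, round(lg)))
  exact[pos] <- abs(lg - round(lg)) < tol & round(lg) >= 1
  list(degree = degree, exact = exact)
}

#' Relationship degree of a pair
#'
#' Degree is defined through kinship, degree = round(-log2(2 * phi)), so
#' that double-path relationships (first cousins, who are separated by four
#' path meioses but share 12.5% in expectation) land on the degree their
#' expected sharing implies. Relationships whose expected sharing is not an
#' exact power of 1/2 (e.g. three-quarter siblings) are assigned the
#' nearest degree and flagged via the `"exact"` attribute.
#'
#' @inheritParams kinship
#' @return An integer degree, or `NA` for unrelated pairs, with attribute
#'   `exact`.
#' @examples
#' # an avuncular pair in a three-generation family
#' ped <- tibble::tibble(
#'   ped = "1",
#'   id = c("g1", "g2", "p", "u", "s", "c"),
#'   father = c(NA, NA, "g1", "g1", NA, "p"),
#'   mother = c(NA, NA, "g2", "g2", NA, "s"),
#'   sex = c(1, 2, 1, 1, 2, 2)
#' )
#' relationship_degree(ped, "u", "c")  # 2
#' @export
relationship_degree <- function(pedigree, id1, id2) {
  phi <- kinship(pedigree, id1, id2)
  d <- degree_from_kinship(phi)
  structure(d$degree, exact = d$exact)
}

#' Pairwise relationship summary for whole pedigrees
#'
#' Tabulates kinship, relationship degree and expected genome sharing for
#' every within-pedigree pair, optionally joined with realized sharing from
#' a true IBD matrix.
#'
#' @inheritParams kinship
#' @param ibd Optional [ibd_matrix] holding per-gene IBD scores; when
#'   given, a `realized_sharing` column (mean per-gene score) is added for
#'   the pairs present in the matrix.
#' @return A tibble with columns `ped`, `id1`, `id2`, `kinship`, `degree`,
#'   `exact`, `expected_sharing` (and `realized_sharing` when `ibd` is
#'   supplied). Unrelated pairs have `degree = NA` and expected sharing 0.
#' @export
relatedness_table <- function(pedigree, ibd = NULL) {
  pedigree <- as_pedigree(pedigree)
  out <- purrr::map_dfr(split(pedigree, pedigree$ped), function(sub) {
    if (nrow(sub) < 2) return(NULL)
    K <- kinship_matrix(sub)
    pr <- which(upper.tri(K), arr.ind = TRUE)
    tibble(ped = sub$ped[1],
           id1 = rownames(K)[pr[, 1]],
           id2 = colnames(K)[pr[, 2]],
           kinship = K[pr])
  })
  d <- degree_from_kinship(out$kinship)
  out$degree <- d$degree
  out$exact <- d$exact
  out$expected_sharing <- ifelse(is.na(out$degree), 0, 0.5^out$degree)
  if (!is.null(ibd)) {
    rs <- realized_sharing(ibd)
    hit <- match(pair_key(out$id1, out$id2), pair_key(rs$id1, rs$id2))
    out$realized_sharing <- rs$realized_sharing[hit]
  }
  out
}

# order-free key for an unordered pair of ids
pair_key <- function(id1, id2) {
  paste(pmin(id1, id2), pmax(id1, id2), sep = "\r")
}

#' Realized genome sharing of pairs from a per-gene IBD matrix
#'
#' The realized genome fraction shared by a pair is the unweighted mean of
#' its per-gene IBD scores (0, 0.5 or 1). With genes treated as point loci
#' this is the quantity compared against the expectation `(1/2)^degree`.
#'
#' @param ibd An [ibd_matrix].
#' @param pairs Optional tibble (`id1`, `id2`) restricting the result; an
#'   error is raised for pairs absent from the matrix.
#' @return A tibble `id1`, `id2`, `realized_sharing`.
#' @export
realized_sharing <- function(ibd, pairs = NULL) {
  stopifnot(inherits(ibd, "ibd_matrix"))
  out <- ibd$pairs
  out$realized_sharing <- unname(rowMeans(ibd$score))
  if (!is.null(pairs)) {
    key <- pair_key(pairs$id1, pairs$id2)
    hit <- match(key, pair_key(out$id1, out$id2))
    if (anyNA(hit)) {
      abort(paste0("pair(s) absent from IBD matrix: ",
                   paste(head(key[is.na(hit)], 5), collapse = ", ")))
    }
    out <- out[hit, ]
  }
  out
}
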