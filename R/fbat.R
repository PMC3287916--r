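#' Family-based association score test (FBAT-style)
#'
#' Implements the score statistic of the classic family-based association
#' test for affected offspring with both parental genotypes observed.
#' With additive coding, each affected offspring contributes its
#' minor-allele dosage X centred at the Mendelian expectation given the
#' parents, E(X | parents) = (g_f + g_m) / 2. Per nuclear family f the
#' contribution is U_f = sum over affected offspring of (X - E); the
#' statistic is U = sum of U_f over informative families with variance
#' either model-based, V = sum of Var(X | parents) over affected
#' offspring (each heterozygous parent contributes 1/4 per offspring), or
#' empirical, V = sum of U_f^2 — the robust choice when several nuclear
#' families come from one extended pedigree and contributions may be
#' correlated. Z = U / sqrt(V) is referred to the standard normal,
#' two-sided.
#'
#' A nuclear family is informative for a SNP when at least one parent is
#' heterozygous, both parental genotypes are present, and at least one
#' affected offspring is genotyped; otherwise the offspring genotype
#' distribution conditional on parents is degenerate and the family
#' contributes nothing.
#'
#' @param families Nuclear families from [split_nuclear()].
#' @param dosage Integer matrix of minor-allele dosages, rows named by
#'   individual id, columns by SNP id.
#' @param affected Tibble (`id`, `affected`) or named logical vector.
#' @param snps SNP ids to test (default: all columns of `dosage`).
#' @param empirical_variance Use the empirical (robust) variance
#'   (default `TRUE`)?
#' @return A tibble of class `fbat_result`, one row per SNP: `snp`,
#'   `n_informative_families`, `n_informative_pedigrees`, `U`, `V`, `Z`,
#'   `p`, `method`. When `V = 0` the SNP is non-testable and `Z`/`p` are
#'   `NA`. Per-family contributions are kept in attribute
#'   `"contributions"` and surfaced by [tidy()].
#' @examples
#' ped <- tibble::tibble(
#'   ped = "1", id = c("f", "m", "c"),
#'   father = c(NA, NA, "f"), mother = c(NA, NA, "m"), sex = c(1, 2, 2)
#' )
#' dos <- matrix(c(1L, 1L, 2L), 3, 1, dimnames = list(c("f", "m", "c"), "s1"))
#' fbat_score(split_nuclear(ped), dos, c(f = FALSE, m = FALSE, c = TRUE))
#' @export
fbat_score <- function(families, dosage, affected, snps = NULL,
                       empirical_variance = TRUE) {
  snps <- snps %||% colnames(dosage)
  if (is.data.frame(affected)) {
    affected <- setNames(affected$affected, affected$id)
  }
  eng <- fbat_engine(families, dosage, snps)
  aff_off <- unname(affected[eng$off_id]) %in% TRUE
  res <- fbat_compute(eng, aff_off, empirical_variance)
  out <- new_tibble(res$table, class = "fbat_result")
  attr(out, "contributions") <- res$contributions
  out
}

# Precompute everything that does not depend on affection status.
fbat_engine <- function(families, dosage, snps) {
  if (nrow(families) == 0) abort("no nuclear family supplied")
  miss <- setdiff(snps, colnames(dosage))
  if (length(miss) > 0) {
    abort(paste0("SNP(s) absent from dosage matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  gf <- genotype_rows(dosage, families$father, snps)
  gm <- genotype_rows(dosage, families$mother, snps)
  E <- (gf + gm) / 2
  het <- (gf == 1L) | (gm == 1L)            # NA-safe below
  per_off_var <- 0.25 * (gf == 1L) + 0.25 * (gm == 1L)
  parents_ok <- !is.na(gf) & !is.na(gm)
  het[!parents_ok] <- FALSE
  per_off_var[!parents_ok] <- 0

  off_id <- unlist(families$offspring, use.names = FALSE)
  fam_of_off <- rep(seq_len(nrow(families)), lengths(families$offspring))
  X <- genotype_rows(dosage, off_id, snps)
  dev <- X - E[fam_of_off, , drop = FALSE]

  list(families = families, snps = snps, E = E, het = het,
       per_off_var = per_off_var, off_id = off_id,
       fam_of_off = fam_of_off, X = X, dev = dev)
}

genotype_rows <- function(dosage, ids, snps) {
  miss <- setdiff(ids, rownames(dosage))
  if (length(miss) > 0) {
    abort(paste0("genotype missing for individual(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  dosage[ids, snps, drop = FALSE]
}

# Core statistic for one affection vector over the engine's offspring.
fbat_compute <- function(eng, aff_off, empirical_variance) {
  n_fam <- nrow(eng$families)
  n_snp <- length(eng$snps)
  aff_num <- as.numeric(aff_off)
  genotyped <- !is.na(eng$X)
  contrib <- eng$dev
  contrib[!genotyped] <- 0
  contrib <- contrib * aff_num           # recycles down rows (offspring)
  U_f <- rowsum(contrib, eng$fam_of_off, reorder = FALSE)
  aff_count <- rowsum(genotyped * aff_num, eng$fam_of_off, reorder = FALSE)
  informative <- eng$het & aff_count > 0
  U_f[!informative] <- 0
  U <- colSums(U_f)
  V <- if (empirical_variance) {
    colSums(U_f^2)
  } else {
    colSums(eng$per_off_var * aff_count * informative)
  }
  Z <- ifelse(V > 0, U / sqrt(V), NA_real_)
  p <- ifelse(is.na(Z), NA_real_, 2 * pnorm(-abs(Z)))
  ped_of_fam <- eng$families$ped
  n_ped <- apply(informative, 2, function(col) {
    length(unique(ped_of_fam[col]))
  })
  list(
    table = tibble(
      snp = eng$snps,
      n_informative_families = as.integer(colSums(informative)),
      n_informative_pedigrees = as.integer(n_ped),
      U = unname(U), V = unname(V), Z = unname(Z), p = unname(p),
      method = if (empirical_variance) "empirical" else "model"
    ),
    contributions = tibble(
      nuc_id = rep(eng$families$nuc_id, times = n_snp),
      ped = rep(ped_of_fam, times = n_snp),
      snp = rep(eng$snps, each = n_fam),
      U_f = as.vector(U_f),
      informative = as.vector(informative)
    )
  )
}

#' @export
tidy.fbat_result <- function(x, ...) attr(x, "contributions")

#' @export
glance.fbat_result <- function(x, ...) {
  tibble(n_snps = nrow(x),
         n_testable = sum(!is.na(x$p)),
         min_p = suppressWarnings(min(x$p, na.rm = TRUE)))
}

#' Is a nuclear family informative for a SNP?
#'
#' @param family One row of [split_nuclear()] output.
#' @param dosage Dosage matrix (see [fbat_score()]).
#' @param affected Named logical or tibble (`id`, `affected`).
#' @param snp A single SNP id.
#' @return `TRUE` when at least one parent is heterozygous (with both
#'   parental genotypes present) and at least one affected offspring is
#'   genotyped.
#' @export
is_informative <- function(family, dosage, affected, snp) {
  res <- fbat_score(family, dosage, affected, snps = snp)
  res$n_informative_families[1] > 0
}

#' Screen variants with the family-based test across replicates
#'
#' Runs the score test for every SNP in every phenotype replicate in
#' which the SNP is informative in at least `min_pedigrees` extended
#' pedigrees (a pedigree counts when at least one of its nuclear families
#' is informative), then ranks SNPs by the minimum p-value across their
#' tested replicates and flags those below `alpha`.
#'
#' @param pedigree A pedigree tibble.
#' @param dosage Dosage matrix (individuals x SNPs).
#' @param phenotypes A `replicate_set` or long tibble (`replicate`, `id`,
#'   `affected`).
#' @param snps SNP ids to screen (e.g. the kept set from
#'   [filter_variants()]).
#' @param min_pedigrees Minimum informative extended pedigrees per
#'   replicate for a SNP to be tested there (default 3).
#' @param alpha Significance cutoff on the minimum p-value (default
#'   0.05).
#' @param empirical_variance Passed to the score test (default `TRUE`).
#' @return An object of class `fbat_screen`: list with
#'   * `summary` — tibble `snp`, `n_replicates_tested`, `min_p`,
#'     `flagged`, `status` (`"tested"` or
#'     `"insufficient informative pedigrees"`),
#'   * `results` — per-replicate test results (long tibble),
#'   * `params`.
#' @export
fbat_screen <- function(pedigree, dosage, phenotypes, snps,
                        min_pedigrees = 3, alpha = 0.05,
                        empirical_variance = TRUE) {
  if (length(snps) == 0) {
    return(structure(list(
      summary = tibble(snp = character(), n_replicates_tested = integer(),
                       min_p = numeric(), flagged = logical(),
                       status = character()),
      results = tibble(),
      params = list(min_pedigrees = min_pedigrees, alpha = alpha,
                    empirical_variance = empirical_variance)
    ), class = "fbat_screen"))
  }
  families <- split_nuclear(pedigree)
  eng <- fbat_engine(families, dosage, snps)
  pheno_long <- as_tibble(phenotypes)
  reps <- unique(pheno_long$replicate)
  res_rows <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    ph <- pheno_long[pheno_long$replicate == reps[i], ]
    aff <- setNames(ph$affected, ph$id)
    aff_off <- unname(aff[eng$off_id]) %in% TRUE
    tab <- fbat_compute(eng, aff_off, empirical_variance)$table
    tab$replicate <- reps[i]
    res_rows[[i]] <- tab
  }
  results <- bind_rows(res_rows)
  tested <- results[results$n_informative_pedigrees >= min_pedigrees &
                      !is.na(results$p), ]
  per_snp <- if (nrow(tested) > 0) {
    tested |>
      group_by(.data$snp) |>
      summarise(n_replicates_tested = n(),
                min_p = min(.data$p), .groups = "drop")
  } else {
    tibble(snp = character(), n_replicates_tested = integer(),
           min_p = numeric())
  }
  summary <- tibble(snp = snps) |>
    left_join(per_snp, by = "snp") |>
    mutate(
      n_replicates_tested = ifelse(is.na(.data$n_replicates_tested), 0L,
                                   .data$n_replicates_tested),
      flagged = !is.na(.data$min_p) & .data$min_p < alpha,
      status = ifelse(.data$n_replicates_tested > 0, "tested",
                      "insufficient informative pedigrees")
    ) |>
    arrange(.data$min_p)
  structure(list(
    summary = summary, results = results,
    params = list(min_pedigrees = min_pedigrees, alpha = alpha,
                  empirical_variance = empirical_variance,
                  n_replicates = length(reps))
  ), class = "fbat_screen")
}

#' @export
print.fbat_screen <- function(x, ...) {
  cat(sprintf("<fbat_screen> %d SNPs, %d flagged at min p < %.3g (min %d informative pedigrees)\n",
              nrow(x$summary), sum(x$summary$flagged), x$params$alpha,
              x$params$min_pedigrees))
  invisible(x)
}

#' @export
tidy.fbat_screen <- function(x, ...) x$summary

#' @export
glance.fbat_screen <- function(x, ...) {
  tibble(n_snps = nrow(x$summary),
         n_tested = sum(x$summary$status == "tested"),
         n_flagged = sum(x$summary$flagged),
         min_pedigrees = x$params$min_pedigrees,
         alpha = x$params$alpha)
}
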