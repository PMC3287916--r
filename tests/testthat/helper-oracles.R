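# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the kinship oracle is a vectorised single-locus
# allele drop, and the FBAT oracle enumerates Mendelian transmissions.

# Monte-Carlo estimate of the kinship coefficient between every pair:
# drop one unlinked locus n_rep times; phi-hat = P(two randomly drawn
# alleles, one per individual, are copies of the same founder allele).
mc_kinship <- function(pedigree, n_rep = 1e5) {
  ids <- pedigree$id
  n <- nrow(pedigree)
  idx <- stats::setNames(seq_len(n), ids)
  pat <- matrix(0L, n, n_rep)
  mat <- matrix(0L, n, n_rep)
  founders <- which(is.na(pedigree$father))
  lab <- 0L
  for (f in founders) {
    pat[f, ] <- lab + 1L
    mat[f, ] <- lab + 2L
    lab <- lab + 2L
  }
  for (i in which(!is.na(pedigree$father))) {
    fa <- idx[[pedigree$father[i]]]
    mo <- idx[[pedigree$mother[i]]]
    pick1 <- stats::runif(n_rep) < 0.5
    pick2 <- stats::runif(n_rep) < 0.5
    pat[i, ] <- ifelse(pick1, pat[fa, ], mat[fa, ])
    mat[i, ] <- ifelse(pick2, pat[mo, ], mat[mo, ])
  }
  # P(random allele of i == random allele of j) at one locus
  phi_hat <- function(i, j) {
    a <- ifelse(stats::runif(n_rep) < 0.5, pat[i, ], mat[i, ])
    b <- ifelse(stats::runif(n_rep) < 0.5, pat[j, ], mat[j, ])
    mean(a == b)
  }
  list(phi_hat = phi_hat, n_rep = n_rep)
}

# Random valid pedigree of at most max_n members: start from founder
# couples and add children of random existing or new parents.
random_small_pedigree <- function(max_n = 12, ped_id = "T") {
  n_target <- sample(6:max_n, 1)
  rows <- data.frame(ped = ped_id, id = c("m1", "f1"),
                     father = NA_character_, mother = NA_character_,
                     sex = c(1L, 2L), stringsAsFactors = FALSE)
  males <- "m1"; females <- "f1"
  k <- 2L
  while (nrow(rows) < n_target) {
    k <- k + 1L
    id <- paste0("i", k)
    if (stats::runif(1) < 0.35) {          # new founder marrying in
      sex <- sample(1:2, 1)
      rows <- rbind(rows, data.frame(ped = ped_id, id = id,
                                     father = NA_character_,
                                     mother = NA_character_, sex = sex,
                                     stringsAsFactors = FALSE))
    } else {                               # child of a random couple
      fa <- sample(males, 1); mo <- sample(females, 1)
      sex <- sample(1:2, 1)
      rows <- rbind(rows, data.frame(ped = ped_id, id = id, father = fa,
                                     mother = mo, sex = sex,
                                     stringsAsFactors = FALSE))
    }
    if (rows$sex[nrow(rows)] == 1L) males <- c(males, id) else females <- c(females, id)
  }
  rows
}

# Exhaustive Mendelian enumeration for one nuclear family: expected value
# and variance of an offspring's minor-allele dosage given the parents,
# from the four equiprobable meiotic outcomes.
enum_transmission <- function(gf, gm) {
  f_alleles <- switch(as.character(gf), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
  m_alleles <- switch(as.character(gm), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
  x <- as.vector(outer(f_alleles, m_alleles, `+`))   # 4 equiprobable
  list(support = sort(unique(x)),
       mean = mean(x),
       var = mean((x - mean(x))^2))
}

# Oracle (U, model V) for a single nuclear family with affected offspring
# dosages `x_aff`.
enum_fbat <- function(gf, gm, x_aff) {
  tr <- enum_transmission(gf, gm)
  stopifnot(all(x_aff %in% tr$support))
  list(U = sum(x_aff - tr$mean), V = length(x_aff) * tr$var)
}

# Build a one-family test fixture in the package's interface terms.
one_family <- function(gf, gm, kids, aff_kids) {
  n_k <- length(kids)
  ped <- tibble::tibble(
    ped = "1",
    id = c("fa", "mo", paste0("k", seq_len(n_k))),
    father = c(NA, NA, rep("fa", n_k)),
    mother = c(NA, NA, rep("mo", n_k)),
    sex = c(1, 2, rep(1, n_k))
  )
  dos <- matrix(as.integer(c(gf, gm, kids)), ncol = 1,
                dimnames = list(ped$id, "s1"))
  aff <- stats::setNames(c(FALSE, FALSE, aff_kids), ped$id)
  list(ped = ped, families = ibdfilter::split_nuclear(ped),
       dosage = dos, affected = aff)
}
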