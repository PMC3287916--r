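test_that("the single-family worked example matches enumeration", {
  # het x het parents, one affected homozygous-minor child:
  # E[X] = 1, Var = 1/2, U = 1
  fx <- one_family(1, 1, kids = 2, aff_kids = TRUE)
  model <- fbat_score(fx$families, fx$dosage, fx$affected,
                      empirical_variance = FALSE)
  expect_equal(model$U, 1)
  expect_equal(model$V, 0.5)
  expect_equal(model$Z, sqrt(2))
  expect_equal(model$p, 2 * pnorm(-sqrt(2)))   # ~0.157

  emp <- fbat_score(fx$families, fx$dosage, fx$affected)
  expect_equal(emp$U, 1)
  expect_equal(emp$V, 1)                       # single family: V = U^2
  expect_equal(emp$p, 2 * pnorm(-1))           # ~0.317
})

test_that("informativeness requires segregation and an affected child", {
  # hom x hom parents: nothing segregates
  fx <- one_family(0, 0, kids = 0, aff_kids = TRUE)
  expect_false(is_informative(fx$families, fx$dosage, fx$affected, "s1"))
  # het x hom with affected child: informative
  fx2 <- one_family(1, 0, kids = 1, aff_kids = TRUE)
  expect_true(is_informative(fx2$families, fx2$dosage, fx2$affected, "s1"))
  # het x het but no affected offspring: zero conditional variance of the
  # affected-only score
  fx3 <- one_family(1, 1, kids = 1, aff_kids = FALSE)
  expect_false(is_informative(fx3$families, fx3$dosage, fx3$affected, "s1"))
  res3 <- fbat_score(fx3$families, fx3$dosage, fx3$affected)
  expect_true(is.na(res3$p))                   # V = 0 -> non-testable
  # missing parental genotype: family silently non-informative
  fx4 <- one_family(1, 1, kids = 2, aff_kids = TRUE)
  fx4$dosage["mo", 1] <- NA
  expect_false(is_informative(fx4$families, fx4$dosage, fx4$affected, "s1"))
})

test_that("offspring at their Mendelian expectation centre the score", {
  # two het x het families, each with one affected child at dosage 1 = E[X]
  ped <- tibble::tibble(
    ped = c("1", "1", "1", "2", "2", "2"),
    id = c("f1", "m1", "k1", "f2", "m2", "k2"),
    father = c(NA, NA, "f1", NA, NA, "f2"),
    mother = c(NA, NA, "m1", NA, NA, "m2"),
    sex = c(1, 2, 1, 1, 2, 2)
  )
  dos <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L), ncol = 1,
                dimnames = list(ped$id, "s1"))
  aff <- stats::setNames(c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE), ped$id)
  res <- fbat_score(split_nuclear(ped), dos, aff, empirical_variance = FALSE)
  expect_equal(res$U, 0)
  expect_equal(res$p, 1)

  # opposite-signed family contributions cancel
  dos2 <- dos
  dos2["k1", 1] <- 2L
  dos2["k2", 1] <- 0L
  res2 <- fbat_score(split_nuclear(ped), dos2, aff)
  expect_equal(res2$U, 0)
  expect_equal(res2$Z, 0)
  expect_equal(res2$p, 1)
  contrib <- tidy(res2)
  expect_equal(sort(contrib$U_f), c(-1, 1))
})

test_that("allele relabelling negates U and preserves the test", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n_fam <- 6
      ped <- tibble::tibble(
        ped = rep(as.character(1:3), each = n_fam / 3 * 4)[1:(4 * n_fam)],
        id = paste0("i", 1:(4 * n_fam)),
        father = NA_character_, mother = NA_character_,
        sex = rep(c(1, 2, 1, 2), n_fam)
      )
      for (f in seq_len(n_fam)) {
        r <- (f - 1) * 4
        ped$father[r + 3:4] <- ped$id[r + 1]
        ped$mother[r + 3:4] <- ped$id[r + 2]
      }
      gf <- sample(0:2, n_fam, TRUE); gm <- sample(0:2, n_fam, TRUE)
      kid <- function(g1, g2) rbinom(1, 1, g1 / 2) + rbinom(1, 1, g2 / 2)
      dos <- integer(4 * n_fam)
      for (f in seq_len(n_fam)) {
        r <- (f - 1) * 4
        dos[r + 1] <- gf[f]; dos[r + 2] <- gm[f]
        dos[r + 3] <- kid(gf[f], gm[f]); dos[r + 4] <- kid(gf[f], gm[f])
      }
      dosage <- matrix(as.integer(dos), ncol = 1,
                       dimnames = list(ped$id, "s1"))
      aff <- stats::setNames(rep(c(FALSE, FALSE, TRUE, sample(c(TRUE, FALSE), 1)),
                                 n_fam), ped$id)
      fams <- split_nuclear(ped)
      for (emp in c(TRUE, FALSE)) {
        a <- fbat_score(fams, dosage, aff, empirical_variance = emp)
        b <- fbat_score(fams, 2L - dosage, aff, empirical_variance = emp)
        expect_equal(b$U, -a$U)
        expect_equal(b$V, a$V)
        expect_equal(abs(b$Z), abs(a$Z))
        expect_equal(b$p, a$p)
      }
      # empirical V is the sum of squared family contributions
      a <- fbat_score(fams, dosage, aff)
      expect_equal(a$V, sum(tidy(a)$U_f^2))
    }
  })
})

test_that("the screen enforces the informative-pedigree minimum", {
  cfg <- sim_config(n_pedigrees = 3, n_genes = 40, n_snps = 120,
                    n_replicates = 6, causal_min_carriers = 5, seed = 25)
  study <- simulate_study(cfg)
  snps <- study$map$snp[order(study$map$maf, decreasing = TRUE)][1:10]
  counts <- integer(0)
  for (mp in c(1, 2, 3)) {
    scr <- fbat_screen(study$pedigree, study$drop$dosage, study$phenotypes,
                       snps, min_pedigrees = mp)
    expect_true(all(scr$summary$status %in%
                      c("tested", "insufficient informative pedigrees")))
    expect_true(all(scr$summary$min_p >= 0 | is.na(scr$summary$min_p)))
    counts <- c(counts, sum(scr$summary$status == "tested"))
    # every tested snp really reached the minimum in some replicate
    tested <- scr$summary$snp[scr$summary$status == "tested"]
    for (s in tested) {
      got <- scr$results$n_informative_pedigrees[scr$results$snp == s]
      expect_true(max(got) >= mp)
    }
  }
  expect_true(all(diff(counts) <= 0))   # stricter minimum, fewer candidates

  # a snp informative nowhere near the minimum is excluded with a reason
  rare <- study$map$snp[which.min(study$map$maf)]
  scr8 <- fbat_screen(study$pedigree, study$drop$dosage, study$phenotypes,
                      rare, min_pedigrees = 3)
  if (scr8$summary$n_replicates_tested[1] == 0) {
    expect_equal(scr8$summary$status[1], "insufficient informative pedigrees")
    expect_false(scr8$summary$flagged[1])
  }
})

test_that("(U, V) match exhaustive transmission enumeration", {
  for (gf in 0:2) for (gm in 0:2) {
    tr <- enum_transmission(gf, gm)
    for (n_off in 1:2) {
      combos <- expand.grid(rep(list(tr$support), n_off))
      for (i in seq_len(nrow(combos))) {
        kids <- as.integer(combos[i, ])
        fx <- one_family(gf, gm, kids = kids, aff_kids = rep(TRUE, n_off))
        res <- fbat_score(fx$families, fx$dosage, fx$affected,
                          empirical_variance = FALSE)
        oracle <- enum_fbat(gf, gm, kids)
        if (res$n_informative_families == 1) {
          expect_equal(res$U, oracle$U)
          expect_equal(res$V, oracle$V)
        } else {
          expect_equal(oracle$V, 0)   # only degenerate families excluded
        }
      }
    }
  }
})
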