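#' Simulate extended pedigrees
#'
#' Builds multi-generation outbred pedigrees by forward growth from one
#' founding couple per pedigree. Every couple has 3-5 children; in the
#' founding generation at least two children marry (a married-in founder of
#' opposite sex) and in later non-terminal generations at least two per
#' couple marry with probability 0.3 (otherwise exactly two), so every
#' branch persists to the last generation. This guarantees relative pairs
#' at degrees 1 through 5 (e.g. second cousins) in every pedigree and, at
#' the default configuration, a total size near 700 individuals over eight
#' pedigrees. No inbreeding loops are ever created: spouses are always new
#' founders.
#'
#' @param config A [sim_config()]. Only the pedigree fields
#'   (`n_pedigrees`, `depth`, `mean_children`) and `seed` are used.
#' @return A pedigree tibble (see [as_pedigree()]) with an extra
#'   `generation` column.
#' @examples
#' ped <- sim_pedigrees(sim_config(n_pedigrees = 2, seed = 7))
#' dplyr::count(ped, ped)
#' @export
sim_pedigrees <- function(config) {
  validate_sim_config(config)
  maybe_with_seed(config$seed, sim_pedigrees_impl(config))
}

sim_pedigrees_impl <- function(config) {
  out <- purrr::map_dfr(seq_len(config$n_pedigrees), function(p) {
    sim_one_pedigree(sprintf("P%02d", p), config$depth, config$mean_children)
  })
  as_pedigree(out)
}

# One pedigree, grown generation by generation. ids are "<ped>_<k>".
sim_one_pedigree <- function(ped_id, depth, mean_children) {
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("%s_%03d", ped_id, counter)
  }
  rows <- list()
  add <- function(id, father, mother, sex, gen) {
    rows[[length(rows) + 1L]] <<- tibble(
      ped = ped_id, id = id, father = father, mother = mother,
      sex = sex, generation = gen
    )
  }
  f1 <- new_id(); m1 <- new_id()
  add(f1, NA, NA, 1L, 1L)
  add(m1, NA, NA, 2L, 1L)
  couples <- list(c(f1, m1))
  p_extra <- (mean_children - 3) / 2
  for (g in seq_len(depth - 1L)) {
    next_couples <- list()
    for (cp in couples) {
      n_child <- 3L + rbinom(1L, 2L, p_extra)
      child_sex <- sample(c(1L, 2L), n_child, replace = TRUE)
      child_ids <- character(n_child)
      for (k in seq_len(n_child)) {
        child_ids[k] <- new_id()
        add(child_ids[k], cp[1], cp[2], child_sex[k], g + 1L)
      }
      if (g + 1L < depth) {
        # children of this couple who marry and found the next generation;
        # two lines always continue so distant-cousin pairs always exist
        n_marry <- min(n_child, 2L + rbinom(1L, 1L, 0.3))
        marry <- sample(seq_len(n_child), n_marry)
        for (k in marry) {
          spouse <- new_id()
          spouse_sex <- if (child_sex[k] == 1L) 2L else 1L
          add(spouse, NA, NA, spouse_sex, g + 1L)
          pair <- if (child_sex[k] == 1L) c(child_ids[k], spouse) else c(spouse, child_ids[k])
          next_couples[[length(next_couples) + 1L]] <- pair
        }
      }
    }
    couples <- next_couples
  }
  bind_rows(rows)
}

# run expr under a temporary seed when one is given
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(seed, expr)
}
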