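#' Validate and normalise a pedigree table
#'
#' A pedigree is an ordinary tibble with one row per individual and columns
#' `ped` (pedigree id), `id`, `father`, `mother` (both `NA` for founders),
#' and `sex` (1 = male, 2 = female). `as_pedigree()` checks structural
#' validity — unique ids, both parents present or both absent, parents that
#' exist in the same pedigree with the right sexes, and no individual being
#' its own ancestor — and adds a derived logical `founder` column.
#'
#' @param x A data frame with columns `ped`, `id`, `father`, `mother`, `sex`.
#'   Parent columns may use `NA`, `"0"` or `0` for "no parent".
#' @return A tibble with columns `ped`, `id`, `father`, `mother`, `sex`,
#'   `founder`, ordered so that parents precede their children.
#' @examples
#' trio <- tibble::tibble(
#'   ped = "1", id = c("f", "m", "c"),
#'   father = c(NA, NA, "f"), mother = c(NA, NA, "m"), sex = c(1, 2, 1)
#' )
#' as_pedigree(trio)
#' @export
as_pedigree <- function(x) {
  needed <- c("ped", "id", "father", "mother", "sex")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ped <- as_tibble(x)
  ped <- ped[c(needed, setdiff(names(ped), c(needed, "founder")))]
  ped$ped <- as.character(ped$ped)
  ped$id <- as.character(ped$id)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  ped$father[ped$father %in% "0"] <- NA_character_
  ped$mother[ped$mother %in% "0"] <- NA_character_
  ped$sex <- as.integer(ped$sex)

  if (anyDuplicated(ped$id)) {
    dup <- unique(ped$id[duplicated(ped$id)])
    abort(paste0("duplicate individual id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(ped$sex %in% c(1L, 2L))) {
    abort("sex must be coded 1 (male) or 2 (female)")
  }
  one_parent <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(one_parent)) {
    abort(paste0("individual(s) with exactly one parent recorded: ",
                 paste(head(ped$id[one_parent], 5), collapse = ", ")))
  }
  ped$founder <- is.na(ped$father)

  idx <- setNames(seq_len(nrow(ped)), ped$id)
  for (col in c("father", "mother")) {
    ref <- ped[[col]][!is.na(ped[[col]])]
    unknown <- setdiff(ref, ped$id)
    if (length(unknown) > 0) {
      abort(paste0(col, " id(s) not present in pedigree: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    same_ped <- ped$ped[idx[ref]] == ped$ped[!is.na(ped[[col]])]
    if (!all(same_ped)) abort("parent belongs to a different pedigree")
  }
  fa <- ped$father[!is.na(ped$father)]
  mo <- ped$mother[!is.na(ped$mother)]
  if (any(ped$sex[idx[fa]] != 1L)) abort("father with sex != 1")
  if (any(ped$sex[idx[mo]] != 2L)) abort("mother with sex != 2")

  ord <- ped_topo_order(ped)   # errors on cycles
  ped <- ped[ord, ]
  class(ped) <- c("tbl_df", "tbl", "data.frame")
  ped
}

# Topological order (parents before children); errors on ancestry cycles.
ped_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  fa <- idx[ped$father]
  mo <- idx[ped$mother]
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    abort(paste0("pedigree contains an ancestry cycle involving: ",
                 paste(head(ped$id[!placed], 5), collapse = ", ")))
  }
  ord
}

#' Read and write LINKAGE-style PED files
#'
#' The dialect is the classic 6-column LINKAGE pre-makeped layout:
#' whitespace-delimited `family individual father mother sex affection`,
#' with `0` meaning "no parent" and sex coded 1 = male / 2 = female. Extra
#' trailing columns are ignored on read. Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @return `read_ped()` returns a validated pedigree tibble (see
#'   [as_pedigree()]) with an extra `affected` column when the affection
#'   column is informative (1/2 coding mapped to FALSE/TRUE, 0 to `NA`).
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) abort(paste0("no pedigree records in ", path))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(paste0("PED line ", which(nf < 6)[1], " has fewer than 6 columns"))
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  out <- tibble(
    ped = m[, 1], id = m[, 2], father = m[, 3], mother = m[, 4],
    sex = as.integer(m[, 5])
  )
  aff <- m[, 6]
  out <- as_pedigree(out)
  affmap <- c("0" = NA, "1" = FALSE, "2" = TRUE)
  out$affected <- unname(affmap[aff[match(out$id, m[, 2])]])
  out
}

#' @rdname read_ped
#' @param pedigree A pedigree tibble (validated with [as_pedigree()]).
#' @param affected Optional named logical vector or tibble (`id`,
#'   `affected`) used to fill the affection column; unknowns are written 0.
#' @param header Optional character vector written as leading `#` comment
#'   lines.
#' @export
write_ped <- function(pedigree, path, affected = NULL, header = NULL) {
  pedigree <- as_pedigree(pedigree)
  aff_code <- rep("0", nrow(pedigree))
  if (!is.null(affected)) {
    if (is.data.frame(affected)) {
      affected <- setNames(affected$affected, affected$id)
    }
    code <- ifelse(is.na(affected), "0", ifelse(affected, "2", "1"))
    hit <- match(pedigree$id, names(affected))
    aff_code[!is.na(hit)] <- code[hit[!is.na(hit)]]
  }
  body <- paste(pedigree$ped, pedigree$id,
                ifelse(is.na(pedigree$father), "0", pedigree$father),
                ifelse(is.na(pedigree$mother), "0", pedigree$mother),
                pedigree$sex, aff_code, sep = "\t")
  if (!is.null(header)) body <- c(paste0("# ", header), body)
  writeLines(body, path)
  invisible(path)
}

#' Decompose extended pedigrees into nuclear families
#'
#' Each mated pair with at least one child becomes one nuclear family; an
#' individual can appear as offspring in one family and as parent in
#' another. Childless pairs are not represented in a pedigree table and so
#' emit nothing.
#'
#' @param pedigree A pedigree tibble.
#' @return A tibble with one row per nuclear family: `nuc_id`, `ped`,
#'   `father`, `mother`, and a list-column `offspring` of child ids.
#' @export
split_nuclear <- function(pedigree) {
  pedigree <- as_pedigree(pedigree)
  kids <- pedigree[!pedigree$founder, ]
  if (nrow(kids) == 0) {
    return(tibble(nuc_id = character(), ped = character(),
                  father = character(), mother = character(),
                  offspring = list()))
  }
  kids |>
    group_by(.data$ped, .data$father, .data$mother) |>
    summarise(offspring = list(.data$id), .groups = "drop") |>
    mutate(nuc_id = paste(.data$father, .data$mother, sep = "+")) |>
    select("nuc_id", "ped", "father", "mother", "offspring")
}
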