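#' Variant filters: gene restriction, population frequency, function
#'
#' Three composable filters over a variant map, applied after the IBD
#' stage has produced a candidate gene set:
#' * `restrict_to_genes()` keeps the SNPs whose gene is in the candidate
#'   set;
#' * `filter_by_maf()` keeps rare SNPs, `maf < threshold` (strict `<`,
#'   so a SNP at exactly the threshold is removed);
#' * `filter_by_function()` keeps nonsynonymous SNPs and errors on any
#'   function label outside {synonymous, nonsynonymous}.
#'
#' The MAF used is the map's population frequency (the generating MAF in
#' synthetic data, standing in for a reference-panel frequency), not a
#' sample estimate. MAF and function filtering commute.
#'
#' @param map A variant map tibble (columns `snp`, `gene`, `maf`, `func`,
#'   ...). Each function returns the filtered map rows, so calls chain
#'   with the pipe.
#' @param genes Character vector of candidate genes.
#' @param threshold MAF cutoff (default 0.10).
#' @return The filtered variant map tibble.
#' @examples
#' cfg <- sim_config(n_genes = 10, n_snps = 50, seed = 2)
#' map <- sim_variant_map(cfg)
#' map |> restrict_to_genes(unique(map$gene)[1:3]) |> filter_by_maf()
#' @export
restrict_to_genes <- function(map, genes) {
  map[map$gene %in% genes, ]
}

#' @rdname restrict_to_genes
#' @export
filter_by_maf <- function(map, threshold = 0.10) {
  map[map$maf < threshold, ]
}

#' @rdname restrict_to_genes
#' @export
filter_by_function <- function(map) {
  bad <- setdiff(unique(map$func), c("synonymous", "nonsynonymous"))
  if (length(bad) > 0) {
    abort(paste0("unknown function label(s): ", paste(bad, collapse = ", ")))
  }
  map[map$func == "nonsynonymous", ]
}

#' Apply the full variant-filter funnel with provenance
#'
#' Runs gene restriction, MAF filtering and function filtering in one
#' call, annotating every SNP of the candidate genes with which filters it
#' passed.
#'
#' @inheritParams restrict_to_genes
#' @param maf_threshold MAF cutoff (default 0.10, strict `<`).
#' @return A tibble of the SNPs in `genes` with logical columns
#'   `pass_maf`, `pass_func`, `kept`, and the stage counts in attribute
#'   `"funnel"` (named vector: `in_genes`, `after_maf`, `after_func`).
#' @export
filter_variants <- function(map, genes, maf_threshold = 0.10) {
  sub <- restrict_to_genes(map, genes)
  sub <- sub |>
    mutate(pass_maf = .data$maf < maf_threshold,
           pass_func = .data$func == "nonsynonymous",
           kept = .data$pass_maf & .data$pass_func)
  bad <- setdiff(unique(sub$func), c("synonymous", "nonsynonymous"))
  if (length(bad) > 0) {
    abort(paste0("unknown function label(s): ", paste(bad, collapse = ", ")))
  }
  attr(sub, "funnel") <- c(in_genes = nrow(sub),
                           after_maf = sum(sub$pass_maf),
                           after_func = sum(sub$pass_maf & sub$pass_func))
  sub
}
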