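#' Tab-separated readers and writers for pipeline tables
#'
#' All bespoke tables travel as UTF-8, LF, tab-separated files whose
#' leading `#` lines carry provenance (writer, seed/config hash when
#' known). `write_tsv_commented()` writes any tibble that way;
#' `read_tsv_commented()` reads one back, skipping comment lines.
#'
#' @param x A data frame.
#' @param path File path.
#' @param header Character vector of comment lines (written as `# ...`).
#' @return The path (writer, invisibly) or a tibble (reader).
#' @export
write_tsv_commented <- function(x, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con, sep = "\n")
  }
  writeLines(paste(names(x), collapse = "\t"), con, sep = "\n")
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_tsv_commented
#' @export
read_tsv_commented <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read and write per-gene IBD score tables
#'
#' Long TSV with columns `id1`, `id2`, `gene`, `score` (scores in
#' \{0, 0.5, 1\}); the interchange form of an [ibd_matrix].
#'
#' @param ibd An [ibd_matrix].
#' @param path File path.
#' @param header Optional `#` comment lines.
#' @export
write_ibd_tsv <- function(ibd, path, header = NULL) {
  stopifnot(inherits(ibd, "ibd_matrix"))
  write_tsv_commented(as_tibble(ibd), path, header = header)
}

#' @rdname write_ibd_tsv
#' @return `read_ibd_tsv()` returns an [ibd_matrix].
#' @export
read_ibd_tsv <- function(path) {
  long <- read_tsv_commented(path)
  needed <- c("id1", "id2", "gene", "score")
  if (!all(needed %in% names(long))) {
    abort("IBD table must have columns id1, id2, gene, score")
  }
  bad <- setdiff(unique(long$score), c(0, 0.5, 1))
  if (length(bad) > 0) {
    abort(paste0("IBD scores outside {0, 0.5, 1}: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  long$key <- pair_key(long$id1, long$id2)
  pairs <- long[!duplicated(long$key), c("id1", "id2", "key")]
  genes <- unique(long$gene)
  score <- matrix(NA_real_, nrow(pairs), length(genes),
                  dimnames = list(pairs$key, genes))
  score[cbind(match(long$key, pairs$key), match(long$gene, genes))] <- long$score
  if (anyNA(score)) abort("IBD table is not complete over pairs x genes")
  new_ibd_matrix(score, pairs[c("id1", "id2")])
}

#' Write every stage output of a pipeline run
#'
#' Emits, under `dir`: `pedigree.ped`, `variant_map.tsv`,
#' `phenotypes.tsv` (long), `ibd_ranking.tsv`, `replicate_genes.tsv`,
#' `variants_filtered.tsv`, `fbat_summary.tsv`, `candidates.tsv`,
#' `funnel.tsv`. Rows are sorted on their key columns so files diff
#' stably; each carries a `#` header with the package version, the config
#' seed (when set) and a hash of the run parameters.
#'
#' @param result An `ibd_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  stopifnot(inherits(result, "ibd_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- result$study$config$seed
  hdr <- c(
    paste0("ibdfilter ", as.character(utils::packageVersion("ibdfilter"))),
    paste0("seed: ", if (is.null(seed)) "unset" else seed),
    paste0("params: ", rlang::hash(result$params))
  )
  p <- function(f) file.path(dir, f)
  write_ped(result$study$pedigree, p("pedigree.ped"), header = hdr)
  write_tsv_commented(arrange(result$study$map, .data$snp), p("variant_map.tsv"), hdr)
  write_tsv_commented(
    arrange(as_tibble(result$study$phenotypes), .data$replicate, .data$id),
    p("phenotypes.tsv"), hdr)
  write_tsv_commented(arrange(result$filter$ranking, .data$gene),
                      p("ibd_ranking.tsv"), hdr)
  write_tsv_commented(arrange(result$filter$genes, .data$replicate, .data$gene),
                      p("replicate_genes.tsv"), hdr)
  write_tsv_commented(arrange(result$variants, .data$snp),
                      p("variants_filtered.tsv"), hdr)
  write_tsv_commented(arrange(result$screen$summary, .data$snp),
                      p("fbat_summary.tsv"), hdr)
  write_tsv_commented(arrange(result$candidates, .data$gene, .data$pos_bp),
                      p("candidates.tsv"), hdr)
  write_tsv_commented(result$funnel, p("funnel.tsv"), hdr)
  invisible(dir)
}

#' Minimal VCF export of simulated genotypes
#'
#' Writes a VCFv4.2 file with GT as the only FORMAT field, deriving
#' genotypes from minor-allele dosages (0 -> 0/0, 1 -> 0/1, 2 -> 1/1).
#' REF/ALT are placeholder alleles A/B since the simulator works at
#' dosage level.
#'
#' @param drop A [gene_drop()] result.
#' @param map The variant map used to generate it.
#' @param path Output path.
#' @export
write_vcf <- function(drop, map, path) {
  stopifnot(inherits(drop, "gene_drop"))
  ids <- drop$ids
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=ibdfilter gene-drop simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(map)), function(i) {
    paste(c(map$chrom[i], map$pos_bp[i], map$snp[i], "A", "B", ".", "PASS",
            paste0("AF=", signif(map$maf[i], 6)), "GT",
            gt[drop$dosage[, map$snp[i]] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
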