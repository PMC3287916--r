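#' Realized versus expected genome sharing by relationship degree
#'
#' Scatter of each pair's realized sharing (mean per-gene IBD score)
#' against its relationship degree, with the theoretical curve
#' `(1/2)^degree` overlaid — the classic picture motivating distant-pair
#' selection: close relatives share too much genome for filtering to
#' help, distant ones share a narrow, informative fraction.
#'
#' @param relatedness Output of [relatedness_table()] with a
#'   `realized_sharing` column (i.e. called with an `ibd` matrix).
#' @return A ggplot object.
#' @export
plot_sharing_by_degree <- function(relatedness) {
  df <- relatedness[!is.na(relatedness$degree) &
                      !is.na(relatedness$realized_sharing), ]
  curve <- tibble(degree = seq(min(df$degree), max(df$degree)),
                  expected = 0.5^seq(min(df$degree), max(df$degree)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree,
                                   y = .data$realized_sharing)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$expected), colour = "red3") +
    ggplot2::geom_point(data = curve,
                        ggplot2::aes(y = .data$expected),
                        colour = "red3", size = 2) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "relationship degree (m)",
                  y = "realized genome sharing",
                  title = "Realized IBD sharing against the (1/2)^m expectation")
}

#' Distribution of gene selection counts across replicates
#'
#' Histogram of the number of phenotype replicates in which each gene was
#' selected by the IBD stage, with the keep threshold marked.
#'
#' @param filter An `ibd_filter` from [ibd_filter_replicates()] (or its
#'   `ranking` tibble plus `replicate_min`).
#' @param replicate_min Keep threshold; taken from the object when given
#'   an `ibd_filter`.
#' @return A ggplot object.
#' @export
plot_replicate_counts <- function(filter, replicate_min = NULL) {
  if (inherits(filter, "ibd_filter")) {
    replicate_min <- replicate_min %||% filter$params$replicate_min
    ranking <- filter$ranking
  } else {
    ranking <- filter
  }
  gg <- ggplot2::ggplot(ranking, ggplot2::aes(x = .data$n_replicates)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35") +
    ggplot2::labs(x = "replicates in which the gene was selected",
                  y = "genes",
                  title = "Gene selection counts across phenotype replicates")
  if (!is.null(replicate_min)) {
    gg <- gg + ggplot2::geom_vline(xintercept = replicate_min - 0.5,
                                   colour = "red3", linetype = 2)
  }
  gg
}

#' @rdname plot_replicate_counts
#' @param object,... An `ibd_pipeline` (autoplot dispatch).
#' @export
autoplot.ibd_pipeline <- function(object, ...) {
  plot_replicate_counts(object$filter)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
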