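#' Rank-value knee plot of Jaccard scores
#'
#' Plots the sorted scores on a log10 axis against rank with the knee
#' threshold, the standard diagnostic for whether same-well bead pairs
#' separate from background.
#'
#' @param values Positive scores (e.g. `jaccard` from [jaccard_pairs()]).
#' @param threshold Optional threshold (e.g. from [knee_threshold()]) drawn
#'   as a horizontal line.
#' @return A ggplot object.
#' @export
plot_knee <- function(values, threshold = NULL) {
  df <- tibble(rank = seq_along(values),
               value = sort(values, decreasing = TRUE))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pair rank", y = "Jaccard index") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Barnyard scatter of species calls
#'
#' @param calls A [classify_species()] result.
#' @return A ggplot object: per-cell unit counts of the two species,
#'   coloured by call.
#' @export
plot_barnyard <- function(calls) {
  sp <- setdiff(names(calls),
                c("cell_barcode", "total", "share_max", "label", "truth"))
  stopifnot(length(sp) == 2L)
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data[[sp[1]]], y = .data[[sp[2]]],
                               colour = .data$label)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = paste(sp[1], "units"), y = paste(sp[2], "units"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a CNV matrix
#'
#' Regions in genomic order against pseudobulks, with the scaled CNV value
#' as fill; optionally annotated with classification labels.
#'
#' @param cnv A `cnv_matrix`.
#' @param classification Optional [iterative_classify()] result used to
#'   order pseudobulks by label.
#' @return A ggplot object.
#' @export
plot_cnv_heatmap <- function(cnv, classification = NULL) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  df <- as_tibble(cnv$values, rownames = "region") |>
    tidyr::pivot_longer(-"region", names_to = "pseudobulk",
                        values_to = "value") |>
    mutate(region = factor(.data$region, levels = rownames(cnv$values)))
  if (!is.null(classification)) {
    ord <- classification |> arrange(.data$label, .data$score)
    df$pseudobulk <- factor(df$pseudobulk, levels = ord$pseudobulk)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$pseudobulk,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = cnv$scale_range) +
    ggplot2::labs(x = "region (genomic order)", y = "pseudobulk",
                  fill = "CNV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
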