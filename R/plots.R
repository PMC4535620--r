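#' Plot a metagene expression landscape
#'
#' 2D colour-grid rendering of one sample's landscape; over/under spot
#' outlines can be overlaid from a classification matrix.
#'
#' @param ls a `som_landscape`.
#' @param cls optional classification matrix from
#'   [classify_metagenes()]; classified units are marked.
#' @return a ggplot object.
#' @export
plot_landscape <- function(ls, cls = NULL) {
  df <- expand.grid(row = seq_len(nrow(ls$grid)),
                    col = seq_len(ncol(ls$grid)))
  df$de <- ls$grid[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$de)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", name = "Δe") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = ls$sample, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cls)) {
    df$class <- cls[cbind(df$row, df$col)]
    marked <- df[df$class != "none", , drop = FALSE]
    if (nrow(marked))
      p <- p + ggplot2::geom_point(
        data = marked,
        ggplot2::aes(shape = .data$class), size = 1, inherit.aes = TRUE)
  }
  p
}

#' MA plot of a differential expression result
#'
#' Mean normalized count (log10 x-axis) against log2 fold change, with
#' significant genes highlighted.
#'
#' @param res a `de_result` from [nb_wald_test()].
#' @param fdr_threshold highlighting threshold (default 0.01).
#' @return a ggplot object.
#' @export
plot_ma <- function(res, fdr_threshold = 0.01) {
  df <- as.data.frame(res)
  df$significant <- df$fdr < fdr_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$baseMean, y = .data$log2FC,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change") +
    ggplot2::theme_classic()
}

#' Plot a subtelomeric neighbour expression profile
#'
#' @param profile a `neighbour_profile` from [neighbour_profile()].
#' @return a ggplot object.
#' @export
plot_neighbour_profile <- function(profile) {
  meta <- c("gene", "offset", "bp_to_telomere", "rank_to_telomere")
  conds <- setdiff(names(profile), meta)
  long <- do.call(rbind, lapply(conds, function(cn)
    data.frame(offset = profile$offset, condition = cn,
               expr = profile[[cn]], stringsAsFactors = FALSE)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset, y = .data$expr,
                                     colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "gene offset from SAg", y = "log10 expression") +
    ggplot2::theme_classic()
}
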