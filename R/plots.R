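#' Blob plot of a metagenome
#'
#' GC fraction against log-scaled coverage, point size by contig length,
#' coloured by taxon call or bin: the diagnostic view in which the
#' mycobiont appears as a linear cloud at 30-50% GC and consistent
#' coverage.
#'
#' @param features Tibble from [compute_contig_features()].
#' @param calls Optional tibble `contig_id`, `taxon_call`.
#' @param bins Optional tibble `contig_id`, `bin`.
#' @return A ggplot object.
#' @export
plot_blob <- function(features, calls = NULL, bins = NULL) {
  df <- features
  if (!is.null(calls)) df <- left_join(df, calls, by = "contig_id")
  if (!is.null(bins)) df <- left_join(df, bins, by = "contig_id")
  df$.colour <- if (!is.null(bins)) factor(df$bin)
                else if (!is.null(calls)) df$taxon_call
                else "contig"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gc, y = .data$coverage)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$length,
                                     colour = .data$.colour), alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "GC fraction", y = "Mean read depth (x)",
                  colour = if (!is.null(bins)) "Bin" else "Taxon") +
    ggplot2::theme_minimal()
}

#' @method autoplot lichen_pcoa
#' @export
autoplot.lichen_pcoa <- function(object, colour = NULL, ...) {
  pts <- object$points
  ve <- object$var_explained
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PCoA 2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    stopifnot(length(colour) == nrow(pts))
    p <- p + ggplot2::aes(colour = colour) + ggplot2::labs(colour = NULL)
  }
  p
}

#' @method autoplot bgc_families
#' @export
autoplot.bgc_families <- function(object, ...) {
  sizes <- tidy(object) |> filter(.data$n_genomes > 0)
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$n_genomes)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey30") +
    ggplot2::labs(x = "Genomes per family", y = "Number of families") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
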