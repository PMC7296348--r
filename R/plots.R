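#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_tile
#'   geom_text geom_errorbar labs scale_fill_brewer theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot PCA sample scores
#'
#' @param object A `cortex_pca` result.
#' @param components Two component indices to plot.
#' @param colour_by Optional named factor/character vector (by sample id)
#'   used to colour points (e.g. cluster labels or outcomes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cortex_pca <- function(object, components = c(1, 2),
                                colour_by = NULL, ...) {
  pcs <- paste0("PC", components)
  dat <- object$scores[, c("sample_id", pcs)]
  names(dat) <- c("sample_id", "x", "y")
  ve <- round(100 * object$variance_explained[components], 1)
  p <- ggplot(dat, aes(x = .data$x, y = .data$y))
  if (!is.null(colour_by)) {
    dat$colour <- colour_by[dat$sample_id]
    p <- ggplot(dat, aes(x = .data$x, y = .data$y, colour = .data$colour)) +
      labs(colour = "group")
  }
  p + geom_point(size = 2) +
    labs(x = sprintf("%s (%.1f%%)", pcs[1], ve[1]),
         y = sprintf("%s (%.1f%%)", pcs[2], ve[2])) +
    theme_minimal()
}

#' Plot Z-scored loadings with highest contributors labeled
#'
#' @param pca A `cortex_pca` result.
#' @param components Two component indices.
#' @param z_threshold Label genes with `|Z|` above this on either component.
#' @return A ggplot.
#' @export
plot_loading_contributors <- function(pca, components = c(1, 2),
                                      z_threshold = 2) {
  pcs <- paste0("PC", components)
  dat <- pca$loading_z[, c("gene", pcs)]
  names(dat) <- c("gene", "z1", "z2")
  lab <- dplyr::filter(dat, abs(.data$z1) > z_threshold |
                              abs(.data$z2) > z_threshold)
  ggplot(dat, aes(x = .data$z1, y = .data$z2)) +
    geom_point(colour = "grey60", size = 1) +
    geom_point(data = lab, colour = "firebrick", size = 1.5) +
    geom_text(data = lab, aes(label = .data$gene), vjust = -0.6, size = 3) +
    labs(x = paste0("Z-scored loading, ", pcs[1]),
         y = paste0("Z-scored loading, ", pcs[2])) +
    theme_minimal()
}

#' Plot atlas mapping scores
#'
#' Heatmap of z-normalized mapping scores, samples by regions.
#'
#' @param object A `cortex_mapping` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cortex_mapping <- function(object, ...) {
  ggplot(object, aes(x = .data$region, y = .data$sample_id,
                     fill = .data$z)) +
    geom_tile() +
    labs(x = "atlas region", y = "sample", fill = "mapping z") +
    theme_minimal()
}

#' Plot per-line outcome frequencies
#'
#' Stacked outcome-frequency bars per line, biased lines marked with an
#' asterisk.
#'
#' @param line_table Output of [line_frequencies()].
#' @return A ggplot.
#' @export
plot_line_frequencies <- function(line_table) {
  freq <- tidyr::pivot_longer(
    line_table[, c("line", paste0("freq_", outcome_levels))],
    -"line", names_to = "outcome", values_to = "frequency",
    names_prefix = "freq_")
  freq$outcome <- factor(freq$outcome, levels = outcome_levels)
  ord <- line_table$line[order(-line_table$freq_dorsalized)]
  freq$line <- factor(freq$line, levels = ord)
  marks <- dplyr::filter(line_table, .data$biased_flag)
  p <- ggplot(freq, aes(x = .data$line, y = .data$frequency,
                        fill = .data$outcome)) +
    geom_col() +
    scale_fill_brewer(palette = "Set2") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    labs(x = "PSC line", y = "outcome frequency")
  if (nrow(marks) > 0) {
    p <- p + geom_text(data = tibble::tibble(line = factor(marks$line, levels = ord)),
                       aes(x = .data$line, y = 1.04, label = "*"),
                       inherit.aes = FALSE, size = 5)
  }
  p
}
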