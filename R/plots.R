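CLASS_COLOURS <- c(
  "C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
  "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4"
)

#' Plot 96-channel mutation spectra
#'
#' The conventional signature barchart: one bar per channel, coloured and
#' grouped by the six substitution classes, faceted by sample or group.
#'
#' @param spectra A `spectrum96` tibble (from [build_spectrum()]) or a tidy
#'   signature table with `channel` and a value column.
#' @param value Name of the value column (default `"count"`).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectra, value = "count") {
  unit <- intersect(c("sample", "group", "component"), names(spectra))[1]
  df <- spectra |>
    mutate(
      channel = factor(.data$channel, levels = channel_levels()),
      class = substr(as.character(.data$channel), 3, 5)
    )
  p <- ggplot(df, aes(x = .data$channel, y = .data[[value]],
                      fill = .data$class)) +
    geom_col(width = 0.7) +
    scale_fill_manual(values = CLASS_COLOURS, name = NULL) +
    labs(x = NULL, y = value) +
    theme_minimal(base_size = 9) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 4,
                                     family = "mono"),
          panel.grid.major.x = element_blank())
  if (!is.na(unit)) p <- p + facet_wrap(unit, ncol = 1, scales = "free_y")
  p
}

#' @rdname plot_spectrum
#' @param object A `mut_nmf` fit; its signatures are drawn.
#' @param ... Unused.
#' @export
autoplot.mut_nmf <- function(object, ...) {
  plot_spectrum(tidy.mut_nmf(object, "signatures"), value = "probability")
}

#' @rdname plot_spectrum
#' @export
autoplot.spectra_pca <- function(object, ...) {
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2,
                            label = .data$sample)) +
    geom_point() +
    labs(
      x = paste0("PC1 (", round(100 * object$explained[1], 1), "%)"),
      y = paste0("PC2 (", round(100 * object$explained[2], 1), "%)")
    ) +
    theme_minimal()
}

#' Plot group mean exposures with SEM error bars
#'
#' @param expo Output of [exposures_by_group()].
#' @return A ggplot object: stacked mean exposures per group, one bar per
#'   group, with SEM whiskers per component.
#' @export
plot_exposures <- function(expo) {
  ggplot(expo, aes(x = .data$group, y = .data$mean_exposure,
                   fill = .data$component)) +
    geom_col(position = position_dodge(width = 0.9)) +
    geom_errorbar(
      aes(ymin = .data$mean_exposure - .data$sem,
          ymax = .data$mean_exposure + .data$sem),
      position = position_dodge(width = 0.9), width = 0.25, na.rm = TRUE
    ) +
    labs(x = NULL, y = "mean SNVs attributed") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot transcriptional strand bias
#'
#' @param sb Output of [strand_bias()].
#' @return A ggplot object comparing transcribed and untranscribed counts
#'   per substitution class.
#' @export
plot_strand_bias <- function(sb) {
  df <- sb |>
    pivot_longer(c("transcribed", "untranscribed"),
                 names_to = "strand", values_to = "n")
  ggplot(df, aes(x = .data$class, y = .data$n, fill = .data$strand)) +
    geom_col(position = position_dodge(width = 0.9)) +
    scale_fill_manual(values = c(transcribed = "#2166AC",
                                 untranscribed = "#B2182B"), name = NULL) +
    labs(x = NULL, y = "SNVs in genes") +
    theme_minimal()
}
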