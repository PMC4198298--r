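#' Plot a Kaplan-Meier curve
#'
#' Step-function survival curves, one per group when the curve is grouped,
#' with censoring ticks.
#'
#' @param object a `km_curve` tibble from [km_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  grouped <- "group" %in% names(object)
  pad <- function(d) {
    # prepend the (0, 1) anchor so the step starts at full survival
    dplyr::bind_rows(d[0, ], tibble(time = 0, survival = 1), d)
  }
  df <- if (grouped) {
    dplyr::group_modify(dplyr::group_by(object, .data$group), ~pad(.x))
  } else {
    pad(object)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(if (grouped) ggplot2::aes(colour = .data$group)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Recurrence-free survival",
                  colour = "Signature group") +
    ggplot2::theme_minimal()
  cens <- object[object$n_censor > 0 & !is.na(object$survival), ]
  if (nrow(cens)) {
    p <- p + ggplot2::geom_point(
      data = cens,
      mapping = if (grouped) ggplot2::aes(colour = .data$group) else NULL,
      shape = 3, size = 1.5)
  }
  p
}

#' Plot a resampling null distribution
#'
#' Histogram of the null statistics with the observed value marked; the
#' one-tailed right-tail p-value is shown in the subtitle.
#'
#' @param object a `resampling_result`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.resampling_result <- function(object, bins = 30, ...) {
  df <- tibble(value = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "black",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic, y = "Null resamples",
      title = "Observed statistic vs resampling null",
      subtitle = sprintf("one-tailed p = %.4g (%d resamples)",
                         object$p, object$n_resamples)) +
    ggplot2::theme_minimal()
}

#' Plot per-cancer differential-expression support for selected genes
#'
#' Tile plot of signed significance (direction at `p_adj < alpha`) per gene
#' and cancer for the genes passing the accordant-direction rule.
#'
#' @param de_results row-bound [paired_de()] tables.
#' @param selection output of [select_common_de()].
#' @param alpha significance threshold used for display.
#' @return a ggplot object.
#' @export
plot_de_support <- function(de_results, selection, alpha = 0.05) {
  df <- de_results[de_results$gene %in% selection$gene, ]
  df$status <- dplyr::case_when(
    is.na(df$p_adj) | df$p_adj >= alpha ~ "n.s.",
    df$direction == "up" ~ "up",
    TRUE ~ "down")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cancer, y = .data$gene,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(up = "#b2182b", down = "#2166ac",
                                          n.s. = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tumor vs normal") +
    ggplot2::theme_minimal()
}
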