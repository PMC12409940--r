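#' Plot a theta-pi ratio scan
#'
#' Manhattan-style track of the windowed wild/cultivated diversity ratio
#' along each chromosome; with a `sweep_calls` object the empirical top-tail
#' threshold is drawn as a horizontal line and called windows are
#' highlighted, mirroring the way sweep scans are usually displayed.
#'
#' @param object A `sweep_scan` tibble or `sweep_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_calls <- function(object, ...) {
  w <- object$windows
  mid <- (w$start + w$end) / 2
  ggplot2::ggplot(w, ggplot2::aes(x = mid / 1e6, y = .data$ratio,
                                  colour = .data$called)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$threshold,
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(theta[pi] ~ "ratio (wild / cultivated)")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sweep_calls
#' @export
autoplot.sweep_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("pi_wild", "pi_cult"),
                            names_to = "pool", values_to = "pi",
                            names_prefix = "pi_")
  mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = mid / 1e6, y = .data$pi,
                                   colour = .data$pool)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(theta[pi] ~ "per bp"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot phenotype distributions by genotype class with LSD letters
#'
#' @param object An `lsd_fit` from [anova_lsd()].
#' @param data Optional original per-sample table to overlay as points
#'   (columns `genotype_class`, `trait_value`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsd_fit <- function(object, data = NULL, ...) {
  g <- tidy(object)
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -0.6, fontface = "bold") +
    ggplot2::labs(x = NULL, y = "trait value",
                  subtitle = sprintf("one-way ANOVA F = %.3g, p = %.2g",
                                     object$f_statistic, object$p_value)) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_jitter(
      data = data,
      ggplot2::aes(x = .data$genotype_class, y = .data$trait_value),
      width = 0.12, alpha = 0.5, inherit.aes = FALSE)
  }
  p
}
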