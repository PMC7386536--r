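#' Plot arm-specific estimates with overlap-level intervals
#'
#' Dot-and-interval plot of the 16 arm means (the structure used to read off
#' pairwise differences by interval overlap). Arms are ordered by estimate;
#' the top set, when present (after [rank_arms()]), is highlighted.
#'
#' @param object An `arm_summary` tibble from [arm_means()] or [rank_arms()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot arm_summary
autoplot.arm_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- sprintf("%2d %s", df$arm, df$pattern)
  df$label <- factor(df$label, levels = df$label[order(df$estimate)])
  has_top <- "in_top_set" %in% names(df)
  fam <- attr(object, "family")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.25) +
    (if (has_top) {
      ggplot2::geom_point(ggplot2::aes(colour = .data$in_top_set), size = 2)
    } else ggplot2::geom_point(size = 2)) +
    ggplot2::labs(
      x = if (identical(fam, "binomial")) "proportion" else "mean count",
      y = "arm (P IG T IS)",
      title = attr(object, "outcome"),
      subtitle = sprintf("%.1f%% intervals: non-overlap = pairwise difference",
                         100 * attr(object, "level"))
    ) +
    ggplot2::theme_minimal()
  if (has_top) p <- p + ggplot2::scale_colour_manual(
    values = c(`TRUE` = "#D55E00", `FALSE` = "grey30"), name = "top set")
  p
}

#' Forest plot of marginal factor effects
#'
#' Standardized mean differences with bootstrap intervals, one panel per
#' outcome, one row per factor.
#'
#' @param effects Tibble from [marginal_effects()] (one or more outcomes).
#' @return A ggplot object.
#' @export
plot_marginal_effects <- function(effects) {
  if (!all(c("factor", "outcome", "smd") %in% names(effects))) {
    abort("`effects` is not a marginal-effects table.")
  }
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$smd, y = .data$factor)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$smd_low, xmax = .data$smd_high), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "standardized mean difference (on - off)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
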