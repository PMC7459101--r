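#' Plot radial distance-index distributions
#'
#' Binned distributions of the normalized distance index (0 = nuclear
#' centre, 1 = periphery), optionally split by condition group and
#' faceted by probe — the standard centre-to-periphery profile plot.
#'
#' @param indices Output of [normalized_distance_index()] (data frame
#'   form), ideally with `group` and `probe_id` columns.
#' @param n_bins Number of equal-width bins.
#' @return A ggplot object.
#' @export
plot_radial_distribution <- function(indices, n_bins = 10) {
  stopifnot("distance_index" %in% names(indices))
  has_group <- "group" %in% names(indices)
  p <- ggplot2::ggplot(indices, ggplot2::aes(x = .data$distance_index)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density),
                   fill = if (has_group) .data$group else NULL),
      breaks = seq(0, 1, length.out = n_bins + 1),
      position = "identity", alpha = 0.55, color = "grey30") +
    ggplot2::labs(x = "normalized distance index (0 = centre, 1 = border)",
                  y = "density", fill = NULL) +
    ggplot2::theme_minimal()
  if ("probe_id" %in% names(indices)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$probe_id))
  }
  p
}

#' Plot K_GOI against neighbourhood K_mean
#'
#' @param k_table Output of [neighborhood_k_mean()].
#' @param correlation Optional `rf_correlation` to annotate.
#' @return A ggplot object.
#' @export
plot_k_correlation <- function(k_table, correlation = NULL) {
  stopifnot(all(c("k_goi", "k_mean") %in% names(k_table)))
  p <- ggplot2::ggplot(k_table,
                       ggplot2::aes(x = .data$k_goi, y = .data$k_mean)) +
    ggplot2::geom_point(size = 2, color = "steelblue") +
    ggplot2::labs(x = expression(K[GOI] ~ "(bits)"),
                  y = expression(K[mean] ~ "(bits)")) +
    ggplot2::theme_minimal()
  if ("gene_symbol" %in% names(k_table)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$gene_symbol),
                                vjust = -0.8, size = 3)
  }
  if (!is.null(correlation)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("Spearman rho = %.2f (95%% CI %.2f-%.2f), p = %.2g",
                         correlation$rho, correlation$ci_low,
                         correlation$ci_high, correlation$p_value))
  }
  p
}

#' Plot per-chromosome activity (up/down counts and grouping)
#'
#' @param activity Output of [chromosome_activity()].
#' @return A ggplot object.
#' @export
plot_chromosome_activity <- function(activity) {
  long <- tidyr::pivot_longer(activity, c("n_up", "n_down"),
                              names_to = "direction", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chromosome, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(n_up = "forestgreen", n_down = "firebrick"),
      labels = c(n_up = "up", n_down = "down")) +
    ggplot2::labs(x = NULL, y = "differential transcripts", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Autoplot a radial distribution summary
#'
#' @param object An `rf_radial_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot rf_radial_summary
#' @export
autoplot.rf_radial_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                               y = .data$fraction)) +
    ggplot2::geom_col(width = diff(range(object$upper - object$lower)) /
                        nrow(object) * 0.95,
                      fill = "steelblue", color = "grey30") +
    ggplot2::labs(x = "normalized distance index", y = "fraction") +
    ggplot2::theme_minimal()
}

#' Autoplot a mobility-threshold analysis
#'
#' Per-locus positional p-value against intra-chromosomal distance with
#' the mobility threshold marked.
#'
#' @param object An `rf_mobility` from [mobility_threshold_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rf_mobility
#' @export
autoplot.rf_mobility <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$distance_mbp,
                               y = -log10(.data$p_value),
                               color = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = attr(object, "threshold_mbp"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dotted") +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene_symbol),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "intra-chromosomal distance (Mbp)",
                  y = expression(-log[10](p)), color = "significant") +
    ggplot2::theme_minimal()
}
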