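#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Correlation-plane scatter plot
#'
#' Scatter of each entity's Spearman correlation with the R enrichment score
#' against its correlation with the P enrichment score — the plot that makes
#' the anti-correlation of the two programmes visible. Works for the gene
#' table or the TF table of [correlation_tables()].
#'
#' @param corr_tbl Tibble with columns `entity`, `s_with_p`, `s_with_r`.
#' @param highlight Optional entity ids drawn in red with labels.
#' @return A ggplot object.
#' @export
plot_correlation_plane <- function(corr_tbl, highlight = NULL) {
  df <- filter(corr_tbl, !is.na(.data$s_with_p), !is.na(.data$s_with_r))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s_with_p,
                                        y = .data$s_with_r)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Spearman correlation with P score",
                  y = "Spearman correlation with R score") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hi <- filter(df, .data$entity %in% highlight)
    p <- p +
      ggplot2::geom_point(data = hi, colour = "red", size = 1.6) +
      ggplot2::geom_text(data = hi, ggplot2::aes(label = .data$entity),
                         colour = "red", vjust = -0.8, size = 3)
  }
  p
}

#' @rdname plot_correlation_plane
#' @importFrom ggplot2 autoplot
#' @param object A `pr_correlations` object.
#' @param table `"genes"` or `"tfs"`.
#' @param ... Passed to [plot_correlation_plane()].
#' @method autoplot pr_correlations
#' @export
autoplot.pr_correlations <- function(object, table = c("tfs", "genes"), ...) {
  table <- match.arg(table)
  plot_correlation_plane(object[[table]], ...)
}

#' Kaplan-Meier curves per stratum
#'
#' @param clinical Data frame with time/event columns and a stratification
#'   column.
#' @param strat Name of the stratification column.
#' @param outcome `"os"` or `"rfs"`.
#' @return A ggplot step-curve object.
#' @export
plot_km <- function(clinical, strat, outcome = c("os", "rfs")) {
  outcome <- match.arg(outcome)
  tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
  df <- purrr::map_dfr(split(clinical, clinical[[strat]]), function(d) {
    km <- kaplan_meier(d[[tcol]], d[[ecol]])
    bind_rows(tibble(time = 0, n_risk = nrow(d), n_event = 0L,
                     n_censor = 0L, survival = 1),
              km) |>
      mutate(group = d[[strat]][1L])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival fraction", colour = strat) +
    ggplot2::theme_minimal()
}

#' Volcano plot of fraction correlations
#'
#' Each point is an immune cell type: Spearman correlation of its fraction
#' with the designated TF's activity score versus -log10 of the BH-adjusted
#' p-value.
#'
#' @param fraction_corr Tibble from [correlate_fractions_with_score()].
#' @param alpha Significance line.
#' @return A ggplot object.
#' @export
plot_fraction_volcano <- function(fraction_corr, alpha = 0.05) {
  df <- filter(fraction_corr, !is.na(.data$s))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s,
                                   y = -log10(.data$q_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = if ("lineage" %in% names(df))
      .data$lineage else NULL)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$cell_type), vjust = -0.7,
                       size = 2.8) +
    ggplot2::labs(x = "Spearman correlation with activity score",
                  y = expression(-log[10]~"BH q"), colour = "lineage") +
    ggplot2::theme_minimal()
}
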