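#' Heatmap of equity-stratified agreement
#'
#' Visualises the output of [equity_stratification()]: one tile per sex and
#' age decade, faceted by feature; strata flagged insufficient are left
#' blank.
#'
#' @param strat tibble from [equity_stratification()].
#' @return a ggplot object.
#' @export
plot_equity <- function(strat) {
  ggplot2::ggplot(dplyr::filter(strat, .data$flag == "ok"),
                  ggplot2::aes(x = .data$decade, y = .data$sex,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature_id)) +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = "age decade", y = NULL,
                  fill = unique(strat$metric)[1],
                  title = "Agreement by sex and age decade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-feature agreement bar chart
#'
#' @param summary result of [agreement_summary()].
#' @return a ggplot object.
#' @export
plot_agreement <- function(summary) {
  per <- summary$per_feature
  ggplot2::ggplot(per, ggplot2::aes(x = stats::reorder(.data$feature_id,
                                                       .data$value),
                                    y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = summary$mean_value, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = unique(per$metric),
                  title = "Per-feature agreement",
                  subtitle = sprintf("dashed line: unweighted mean %.2f",
                                     summary$mean_value)) +
    ggplot2::theme_minimal()
}
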