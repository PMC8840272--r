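#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot of a block profile
#'
#' Matched cross-block |correlations| per candidate component count, the
#' figure used to pick the number of independent components: the optimum is
#' the largest j whose matches all stay high.
#'
#' @param object an [ica_by_blocks()] profile.
#' @param threshold optional horizontal reference line.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ica_block_profile
#' @export
autoplot.ica_block_profile <- function(object, threshold = 0.8, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$abs_corr)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(
      data = dplyr::summarise(dplyr::group_by(df, .data$j),
                              abs_corr = min(.data$abs_corr),
                              .groups = "drop"),
      linetype = 2) +
    ggplot2::scale_x_continuous(breaks = unique(df$j)) +
    ggplot2::labs(x = "number of independent components (j)",
                  y = "matched cross-block |correlation|") +
    ggplot2::ylim(0, 1)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, colour = "grey50")
  }
  p
}

#' Map plot of component labels or subregions
#'
#' @param object a `vh_label_map` or `vh_subregions`.
#' @param ... unused.
#' @return A ggplot tile map.
#' @method autoplot vh_label_map
#' @export
autoplot.vh_label_map <- function(object, ...) {
  fill <- if ("subregion" %in% names(object)) "subregion" else "label"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = factor(.data[[fill]]))) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(fill = fill, x = NULL, y = NULL)
}

#' @rdname autoplot.vh_label_map
#' @method autoplot vh_subregions
#' @export
autoplot.vh_subregions <- autoplot.vh_label_map

#' Yield series with its fitted trend
#'
#' @param object a [detrend_yield()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot yield_series
#' @export
autoplot.yield_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$yield)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$yield)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "steelblue") +
    ggplot2::labs(y = "yield (t/ha)", x = NULL)
}

#' Evaluation report plots
#'
#' Grouped bars of subregional vs one-fits-all test RMSE per case, plus the
#' sorted improvement curve, mirroring the standard presentation of the
#' comparison.
#'
#' @param object a `vh_eval` from [one_fits_all_comparison()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot vh_eval
#' @export
autoplot.vh_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("subregion", "season", "rmse_sub", "rmse_ofa")],
    cols = c("rmse_sub", "rmse_ofa"),
    names_to = "model", values_to = "rmse")
  df$model <- ifelse(df$model == "rmse_sub", "subregional", "one-fits-all")
  ggplot2::ggplot(df, ggplot2::aes(x = interaction(.data$subregion, .data$season),
                                   y = .data$rmse, fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "subregion.season", y = "test RMSE (t/ha)", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.vh_eval
#' @param report a `vh_eval`.
#' @export
plot_improvement_curve <- function(report) {
  df <- tibble::as_tibble(report)
  df <- dplyr::arrange(df, .data$improvement_rmse_pct)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$improvement_rmse_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "model (sorted)", y = "subregional improvement (%)")
}
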