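#' Boxplots of per-vertebra Dice and Hausdorff values
#'
#' Mirrors the standard quantitative-assessment figure: one box per
#' approach and metric. Accepts a single `metrics_tbl` (via `autoplot()`)
#' or a named list of them, one per approach.
#'
#' @param metrics Named list of `metrics_tbl` objects (names = approaches).
#' @return A ggplot object.
#' @export
plot_metric_boxplots <- function(metrics) {
  if (inherits(metrics, "metrics_tbl")) metrics <- list(result = metrics)
  df <- dplyr::bind_rows(lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    tibble::tibble(approach = nm,
                   metric = rep(c("DSC", "HD (mm)"), each = nrow(m)),
                   value = c(m$dsc, m$hd_mm))
  }))
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$approach, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-vertebra segmentation performance") +
    ggplot2::theme_minimal()
}

#' @rdname plot_metric_boxplots
#' @param object A `metrics_tbl`.
#' @param ... Ignored.
#' @export
autoplot.metrics_tbl <- function(object, ...) {
  plot_metric_boxplots(list(result = object))
}

#' Stacked rating bars of a review analysis
#'
#' Rating distribution (1 = obvious errors .. 4 = precise) per contour
#' source, as proportions.
#'
#' @param analysis A `review_analysis` from [analyze_review()].
#' @return A ggplot object.
#' @export
plot_review_ratings <- function(analysis) {
  stopifnot(inherits(analysis, "review_analysis"))
  df <- dplyr::mutate(
    dplyr::group_by(analysis$ratings, .data$source),
    prop = .data$n / sum(.data$n)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$prop,
                                   fill = .data$rating)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", name = "Rating") +
    ggplot2::labs(x = NULL, y = "Proportion of contours",
                  title = "Subjective contour ratings by source") +
    ggplot2::theme_minimal()
}

#' @rdname plot_review_ratings
#' @param object A `review_analysis`.
#' @param ... Ignored.
#' @export
autoplot.review_analysis <- function(object, ...) plot_review_ratings(object)
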