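#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for segmentation and review objects
#'
#' `tidy()` returns the per-unit tibble of an object (instances of a
#' segmentation, statistical tests of a review analysis); `glance()`
#' returns a one-row summary.
#'
#' @param x An `instance_seg`, `labeled_instance_seg`, `metrics_tbl` or
#'   `review_analysis`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.instance_seg <- function(x, ...) x$table

#' @rdname tidy.instance_seg
#' @export
glance.instance_seg <- function(x, ...) {
  tibble::tibble(
    n_instances = nrow(x$table),
    foreground_voxels = sum(x$table$n_voxels),
    n_edge_contact = sum(x$table$edge_contact),
    n_log_actions = nrow(x$log)
  )
}

#' @rdname tidy.instance_seg
#' @export
glance.labeled_instance_seg <- function(x, ...) {
  dplyr::mutate(glance.instance_seg(x),
                n_anchors = sum(x$table$anchor),
                levels = paste(x$table$level_name, collapse = ","))
}

#' @rdname tidy.instance_seg
#' @export
glance.metrics_tbl <- function(x, ...) {
  tibble::tibble(
    n_vertebrae = nrow(x),
    labeling_accuracy = mean(x$label_correct),
    n_offset_attributed = sum(x$offset_attributed),
    median_dsc = stats::median(x$dsc),
    median_hd_mm = stats::median(x$hd_mm, na.rm = TRUE),
    n_hd_missing = sum(x$hd_missing)
  )
}

#' @rdname tidy.instance_seg
#' @export
tidy.review_analysis <- function(x, ...) x$tests

#' @rdname tidy.instance_seg
#' @export
glance.review_analysis <- function(x, ...) {
  acc <- x$acceptability
  tibble::tibble(
    n_items = x$identification$n,
    identification_accuracy = x$identification$accuracy,
    acceptability_human = acc$acceptable[acc$source == "human"],
    acceptability_automatic = acc$acceptable[acc$source == "automatic"]
  )
}
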