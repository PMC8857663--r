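#' Consensus vertebral level of one instance
#'
#' The modal nonzero level among the instance's voxels in the level-coded
#' prediction, with its consensus fraction: modal-level voxels divided by
#' instance voxels overlapping any nonzero prediction. An instance with no
#' overlap returns `NA`. Predictions at or above the anchor threshold
#' (default 0.95) are trusted as anchors for propagation.
#'
#' @param mask Logical 3-D array, the instance's voxel set.
#' @param level_pred Level-coded [labelmap3d()] on the same grid.
#' @return List with `level_code`, `level_name`, `confidence`.
#' @examples
#' lp <- labelmap3d(array(13L, c(2, 2, 2)), semantics = "level")
#' level_consensus(array(TRUE, c(2, 2, 2)), lp)  # L1, confidence 1
#' @export
level_consensus <- function(mask, level_pred) {
  stopifnot(is.logical(mask), inherits(level_pred, "labelmap3d"))
  if (!identical(dim(mask), dim(level_pred$values))) {
    stop("Grids are misaligned: shapes differ")
  }
  v <- level_pred$values[mask]
  nz <- v[v > 0L]
  if (!length(nz)) {
    return(list(level_code = NA_integer_, level_name = NA_character_,
                confidence = NA_real_))
  }
  counts <- tabulate(nz, nbins = 17L)
  code <- which.max(counts)  # ties to the more cranial (lower) code
  list(level_code = as.integer(code), level_name = level_name(code),
       confidence = counts[code] / length(nz))
}

consensus_table <- function(iseg, level_pred, anchor_threshold) {
  rows <- lapply(iseg$table$instance_id, function(i) {
    cs <- level_consensus(instance_mask(iseg, i), level_pred)
    tibble::tibble(instance_id = i, level_code = cs$level_code,
                   confidence = cs$confidence,
                   anchor = !is.na(cs$confidence) &&
                     cs$confidence >= anchor_threshold)
  })
  dplyr::bind_rows(rows)
}

#' Propagate vertebral levels from anchor instances
#'
#' Anchor instances keep their consensus level; every other instance gets
#' the level implied by counting positions from its nearest anchor along
#' the craniocaudal ordering (one level per position). When equidistant
#' anchors imply conflicting levels, the higher-confidence anchor wins,
#' ties going to the more superior anchor; overridden implications are
#' logged. Propagation past T1 or L5 is an error, as is the absence of any
#' anchor.
#'
#' @param iseg An `instance_seg` (craniocaudally ordered instances).
#' @param anchors Tibble with `instance_id`, `level_code`, `confidence`,
#'   `anchor` as produced by the consensus step.
#' @return A `labeled_instance_seg`: the input segmentation whose table
#'   gains `level_code`, `level_name`, `confidence`, `anchor`.
#' @export
propagate_labels <- function(iseg, anchors) {
  stopifnot(inherits(iseg, "instance_seg"))
  tab <- dplyr::left_join(iseg$table, anchors, by = "instance_id")
  log <- iseg$log
  anc <- tab[which(tab$anchor %in% TRUE & !is.na(tab$level_code)), ]
  if (!nrow(anc)) {
    stop("No anchor instances: cannot propagate vertebral levels")
  }
  n <- nrow(tab)
  assigned <- integer(n)
  for (j in seq_len(n)) {
    if (isTRUE(tab$anchor[j])) {
      assigned[j] <- tab$level_code[j]
      next
    }
    dist <- abs(anc$instance_id - tab$instance_id[j])
    near <- anc[dist == min(dist), , drop = FALSE]
    implied <- near$level_code + (tab$instance_id[j] - near$instance_id)
    if (length(unique(implied)) > 1L) {
      pick <- order(-near$confidence, near$instance_id)[1]
      log <- log_action(log, "propagate", "anchor_conflict",
                        tab$instance_id[j], tab$n_voxels[j],
                        sprintf("implied levels {%s}; kept anchor %d",
                                paste(implied, collapse = ","),
                                near$instance_id[pick]))
    } else pick <- 1L
    assigned[j] <- implied[pick]
  }
  if (any(assigned < 1L | assigned > 17L)) {
    stop("Label propagation ran past T1 or L5 (implied code outside 1..17)")
  }
  if (any(diff(assigned) <= 0)) {
    warning("Assigned levels are not strictly increasing craniocaudally; ",
            "check anchors")
    log <- log_action(log, "propagate", "non_monotone_levels", NA_integer_,
                      NA_integer_, paste(assigned, collapse = ","))
  }
  tab$level_code <- as.integer(assigned)
  tab$level_name <- level_name(assigned)
  tab$anchor <- tab$anchor %in% TRUE
  out <- iseg
  out$table <- tab
  out$log <- log
  class(out) <- c("labeled_instance_seg", "instance_seg")
  out
}

#' Sequential and combined labeling approaches
#'
#' `sequential_approach()` takes geometry from the binary network's
#' prediction (refined) and levels from the labeling network's prediction
#' (consensus + propagation). `combined_approach()` uses a single
#' level-coded prediction for both: it is binarized, refined identically,
#' then re-labeled against the original level prediction. Both share all
#' refinement code.
#'
#' @param binary_pred Binary [labelmap3d()] (sequential only).
#' @param level_pred Level-coded [labelmap3d()].
#' @param config A [refine_config()].
#' @return A `labeled_instance_seg`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_vertebrae = 3, seed = 5))
#' pred <- corrupt_prediction(ph$instances, ph$levels, corruption_spec())
#' sequential_approach(pred$binary, pred$level)$table
#' @export
sequential_approach <- function(binary_pred, level_pred,
                                config = refine_config()) {
  stopifnot(inherits(binary_pred, "labelmap3d"),
            inherits(level_pred, "labelmap3d"))
  stop_if_misaligned(binary_pred, level_pred)
  iseg <- refine_binary(binary_pred, config)
  cons <- consensus_table(iseg, level_pred, config$anchor_threshold)
  propagate_labels(iseg, cons)
}

#' @rdname sequential_approach
#' @export
combined_approach <- function(level_pred, config = refine_config()) {
  stopifnot(inherits(level_pred, "labelmap3d"))
  if (level_pred$semantics != "level") {
    stop("combined_approach needs a level-coded labelmap")
  }
  binary <- labelmap3d(array(as.integer(level_pred$values > 0L),
                             dim(level_pred$values)),
                       spacing = level_pred$spacing,
                       origin = level_pred$origin, semantics = "binary")
  iseg <- refine_binary(binary, config)
  cons <- consensus_table(iseg, level_pred, config$anchor_threshold)
  propagate_labels(iseg, cons)
}

#' Voxelwise level-coded labelmap of a labeled segmentation
#'
#' Each instance's voxels receive its assigned level code; background is 0.
#'
#' @param lseg A `labeled_instance_seg`.
#' @return A level-coded [labelmap3d()].
#' @export
as_level_labelmap <- function(lseg) {
  stopifnot(inherits(lseg, "labeled_instance_seg"))
  out <- array(0L, dim(lseg$labels))
  code_of <- integer(max(lseg$table$instance_id))
  code_of[lseg$table$instance_id] <- lseg$table$level_code
  fg <- lseg$labels > 0L
  out[fg] <- code_of[lseg$labels[fg]]
  labelmap3d(out, spacing = lseg$spacing, origin = lseg$origin,
             semantics = "level")
}
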