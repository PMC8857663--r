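#' Refinement configuration
#'
#' Tunable parameters of the binary-segmentation refinement. The criteria
#' kinds (size, spine-axis position, inter-region distance, watershed
#' splitting of over-tall regions) are fixed; all thresholds are exposed
#' here.
#'
#' @param connectivity Voxel neighborhood for components: 6 or 26.
#' @param min_size_cm3,max_size_cm3 Plausible vertebral-body volume range.
#' @param edge_min_factor Edge-contacting (partially visible) instances are
#'   exempt from the minimum down to `edge_min_factor * min_size_cm3`.
#' @param axis_tolerance_mm Maximum lateral deviation of an instance
#'   centroid from the fitted craniocaudal spine axis.
#' @param expected_height_mm Typical craniocaudal body height.
#' @param fusion_factor An instance is a fusion suspect when its
#'   craniocaudal extent exceeds `fusion_factor * expected_height_mm`.
#' @param marker_suppression_factor Watershed markers closer than
#'   `marker_suppression_factor * expected_height_mm` along the craniocaudal
#'   axis are suppressed (keeps one marker per body center).
#' @param split Logical; set `FALSE` to disable watershed splitting (used to
#'   study the downstream offset-by-one labeling failure).
#' @param anchor_threshold Consensus fraction at or above which a level
#'   prediction is trusted as an anchor (default 0.95).
#' @return A `refine_config` list.
#' @export
refine_config <- function(connectivity = 26, min_size_cm3 = 5,
                          max_size_cm3 = 120, edge_min_factor = 0.25,
                          axis_tolerance_mm = 25, expected_height_mm = 28,
                          fusion_factor = 1.6, marker_suppression_factor = 0.8,
                          split = TRUE, anchor_threshold = 0.95) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  stopifnot(min_size_cm3 > 0, max_size_cm3 > min_size_cm3,
            edge_min_factor >= 0, edge_min_factor <= 1,
            axis_tolerance_mm > 0, expected_height_mm > 0, fusion_factor > 1,
            marker_suppression_factor > 0,
            anchor_threshold > 0, anchor_threshold <= 1)
  structure(list(
    connectivity = as.integer(connectivity), min_size_cm3 = min_size_cm3,
    max_size_cm3 = max_size_cm3, edge_min_factor = edge_min_factor,
    axis_tolerance_mm = axis_tolerance_mm,
    expected_height_mm = expected_height_mm, fusion_factor = fusion_factor,
    marker_suppression_factor = marker_suppression_factor,
    split = isTRUE(split), anchor_threshold = anchor_threshold
  ), class = "refine_config")
}

new_instance_seg <- function(labels, spacing, origin, log = NULL) {
  labels <- relabel_craniocaudal(labels, spacing)
  d <- dim(labels)
  ids <- sort(unique(labels[labels > 0L]))
  rows <- lapply(ids, function(i) {
    w <- which(labels == i)
    ind <- arrayInd(w, d)
    tibble::tibble(
      instance_id = i,
      n_voxels = length(w),
      volume_mm3 = length(w) * prod(spacing),
      centroid_x_mm = mean(ind[, 1] - 1) * spacing[1],
      centroid_y_mm = mean(ind[, 2] - 1) * spacing[2],
      centroid_z_mm = mean(ind[, 3] - 1) * spacing[3],
      z_extent_mm = (diff(range(ind[, 3])) + 1) * spacing[3],
      edge_contact = any(ind == 1L) || any(sweep(ind, 2, d, `==`))
    )
  })
  tab <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    instance_id = integer(), n_voxels = integer(), volume_mm3 = numeric(),
    centroid_x_mm = numeric(), centroid_y_mm = numeric(),
    centroid_z_mm = numeric(), z_extent_mm = numeric(), edge_contact = logical()
  )
  structure(list(labels = labels, spacing = spacing, origin = origin,
                 table = tab, log = log %||% empty_refine_log()),
            class = "instance_seg")
}

empty_refine_log <- function() {
  tibble::tibble(step = character(), action = character(),
                 instance_id = integer(), n_voxels = integer(),
                 detail = character())
}

log_action <- function(log, step, action, instance_id, n_voxels, detail = "") {
  dplyr::bind_rows(log, tibble::tibble(
    step = step, action = action, instance_id = as.integer(instance_id),
    n_voxels = as.integer(n_voxels), detail = detail
  ))
}

# Renumber positive labels 1..n from cranial (highest z centroid) to caudal.
relabel_craniocaudal <- function(labels, spacing) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(labels)
  d <- dim(labels)
  zc <- vapply(ids, function(i) {
    mean(arrayInd(which(labels == i), d)[, 3])
  }, numeric(1))
  new_id <- integer(max(ids))
  new_id[ids[order(-zc)]] <- seq_along(ids)
  out <- labels
  fg <- labels > 0L
  out[fg] <- new_id[labels[fg]]
  out
}

#' @export
print.instance_seg <- function(x, ...) {
  cat("<instance_seg> ", nrow(x$table), " instance(s), spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Connected components of a binary segmentation
#'
#' Maximal connected foreground components under 6- or 26-connectivity.
#' Instance ids are deterministic: 1..n ordered cranial to caudal by
#' centroid position along axis 3.
#'
#' @param binary Binary [labelmap3d()].
#' @param connectivity 6 or 26.
#' @return An `instance_seg`: instance-coded label array plus a tibble of
#'   per-instance geometry (`$table`) and an action log (`$log`).
#' @export
extract_components <- function(binary, connectivity = 26) {
  stopifnot(inherits(binary, "labelmap3d"))
  if (binary$semantics != "binary") stop("extract_components needs a binary labelmap")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  d <- dim(binary$values)
  lab <- array(cc_label_cpp(binary$values > 0L, as.integer(d),
                            as.integer(connectivity)), d)
  new_instance_seg(lab, binary$spacing, binary$origin)
}

#' Filter vertebra candidates by size and spine-axis position
#'
#' Keeps instances whose volume lies in the plausible range (edge-contacting
#' instances are exempt down to a reduced minimum, since partially visible
#' vertebrae are legitimately small), then removes instances whose centroid
#' deviates from a smooth craniocaudal spine axis, fitted through the
#' centroids of the size-passing candidates, by more than the tolerance.
#' Removed voxels are dropped from the foreground; every removal is logged.
#'
#' @param iseg An `instance_seg`.
#' @param config A [refine_config()].
#' @return A filtered `instance_seg`.
#' @export
filter_candidates <- function(iseg, config = refine_config()) {
  stopifnot(inherits(iseg, "instance_seg"), inherits(config, "refine_config"))
  tab <- iseg$table
  if (!nrow(tab)) return(iseg)
  labels <- iseg$labels
  log <- iseg$log
  min_mm3 <- config$min_size_cm3 * 1000
  max_mm3 <- config$max_size_cm3 * 1000

  size_ok <- (tab$volume_mm3 >= min_mm3 & tab$volume_mm3 <= max_mm3) |
    (tab$edge_contact & tab$volume_mm3 >= config$edge_min_factor * min_mm3 &
       tab$volume_mm3 <= max_mm3)
  for (i in tab$instance_id[!size_ok]) {
    log <- log_action(log, "filter", "remove_size", i,
                      tab$n_voxels[tab$instance_id == i],
                      sprintf("volume %.0f mm3 outside [%.0f, %.0f] mm3",
                              tab$volume_mm3[tab$instance_id == i],
                              min_mm3, max_mm3))
  }
  keep <- tab$instance_id[size_ok]

  # spine-axis filter: smooth lateral curve x(z), y(z) through size-passers
  if (length(keep) >= 3L) {
    sub <- tab[tab$instance_id %in% keep, ]
    deg <- min(2L, length(unique(sub$centroid_z_mm)) - 1L)
    if (deg >= 1L) {
      fx <- stats::lm(centroid_x_mm ~ stats::poly(centroid_z_mm, deg), data = sub)
      fy <- stats::lm(centroid_y_mm ~ stats::poly(centroid_z_mm, deg), data = sub)
      dev <- sqrt(stats::residuals(fx)^2 + stats::residuals(fy)^2)
      off_axis <- sub$instance_id[dev > config$axis_tolerance_mm]
      for (i in off_axis) {
        log <- log_action(log, "filter", "remove_off_axis", i,
                          sub$n_voxels[sub$instance_id == i],
                          sprintf("axis deviation %.1f mm > %.1f mm",
                                  dev[sub$instance_id == i],
                                  config$axis_tolerance_mm))
      }
      keep <- setdiff(keep, off_axis)
    }
  }

  removed <- setdiff(tab$instance_id, keep)
  if (length(removed)) labels[labels %in% removed] <- 0L
  new_instance_seg(labels, iseg$spacing, iseg$origin, log)
}

#' Split fused vertebrae by marker-controlled watershed
#'
#' Instances whose craniocaudal extent exceeds
#' `fusion_factor * expected_height_mm` are suspected fusions and
#' partitioned by a watershed flood on the negated interior Euclidean
#' distance transform. Markers are the per-slice distance maxima after
#' craniocaudal suppression of peaks closer than
#' `marker_suppression_factor * expected_height_mm` (ties broken by greater
#' distance, then lower slice index), giving one marker per body center.
#' The parts form an exact partition of the suspect's voxel set. A suspect
#' with a single surviving marker is passed through unchanged with a logged
#' warning.
#'
#' @inheritParams filter_candidates
#' @return An `instance_seg` with fused instances split.
#' @export
split_fused <- function(iseg, config = refine_config()) {
  stopifnot(inherits(iseg, "instance_seg"), inherits(config, "refine_config"))
  tab <- iseg$table
  if (!nrow(tab)) return(iseg)
  labels <- iseg$labels
  log <- iseg$log
  d <- dim(labels)
  sp <- iseg$spacing
  height_cut <- config$fusion_factor * config$expected_height_mm
  suspects <- tab$instance_id[tab$z_extent_mm > height_cut]
  next_id <- max(tab$instance_id) + 1L

  for (i in suspects) {
    w <- which(labels == i)
    ind <- arrayInd(w, d)
    lo <- pmax(apply(ind, 2, min) - 1L, 1L)
    hi <- pmin(apply(ind, 2, max) + 1L, d)
    cd <- hi - lo + 1L
    crop <- array(labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == i, cd)
    interior <- array(edt_to_set_cpp(!crop, as.integer(cd), sp), cd)
    markers <- watershed_markers(crop, interior, sp,
                                 config$marker_suppression_factor *
                                   config$expected_height_mm)
    if (max(markers) < 2L) {
      warning("Fusion suspect instance ", i,
              " has a single distance peak; passed through unchanged")
      log <- log_action(log, "split", "unsplittable_suspect", i, length(w),
                        "single distance-transform peak")
      next
    }
    parts <- array(watershed_flood_cpp(-interior, markers, crop,
                                       as.integer(cd),
                                       as.integer(config$connectivity)), cd)
    sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sel <- crop & parts > 0L
    sub[sel] <- next_id + parts[sel] - 1L
    if (any(crop & parts == 0L)) {
      # unreachable under connected input; keep voxels with original id
      sub[crop & parts == 0L] <- i
    }
    labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
    log <- log_action(log, "split", "watershed_split", i, length(w),
                      sprintf("split into %d parts", max(parts)))
    next_id <- next_id + max(parts)
  }
  new_instance_seg(labels, sp, iseg$origin, log)
}

# Markers: per craniocaudal slice take the in-mask distance maximum; keep
# slices that are local maxima of that profile, then greedily select by
# (distance desc, slice asc) suppressing slices within `suppress_mm`.
watershed_markers <- function(mask, interior, sp, suppress_mm) {
  cd <- dim(mask)
  prof <- vapply(seq_len(cd[3]), function(k) {
    v <- interior[, , k][mask[, , k]]
    if (length(v)) max(v) else -Inf
  }, numeric(1))
  nz <- which(is.finite(prof))
  peaks <- nz[vapply(nz, function(k) {
    lo <- if (k > 1) prof[k - 1] else -Inf
    hi <- if (k < cd[3]) prof[k + 1] else -Inf
    prof[k] >= lo && prof[k] >= hi
  }, logical(1))]
  ord <- peaks[order(-prof[peaks], peaks)]
  chosen <- integer(0)
  for (k in ord) {
    if (!length(chosen) || all(abs(k - chosen) * sp[3] >= suppress_mm)) {
      chosen <- c(chosen, k)
    }
  }
  chosen <- sort(chosen)
  markers <- array(0L, cd)
  for (m in seq_along(chosen)) {
    k <- chosen[m]
    slice <- interior[, , k]
    slice[!mask[, , k]] <- -Inf
    best <- which.max(slice)  # first (lowest linear index) maximum
    ij <- arrayInd(best, cd[1:2])
    markers[ij[1], ij[2], k] <- m
  }
  markers
}

#' Refine a binary vertebra segmentation into instances
#'
#' The full refinement: connected components, candidate filtering by size
#' and spine-axis position, watershed splitting of fusion suspects, and a
#' second filtering pass over the split parts. Never adds foreground;
#' idempotent on its own output; every destructive action is logged.
#'
#' @param binary Binary [labelmap3d()].
#' @param config A [refine_config()].
#' @return An `instance_seg`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_vertebrae = 3, seed = 2))
#' pred <- corrupt_prediction(ph$instances, ph$levels, corruption_spec())
#' refine_binary(pred$binary)$table
#' @export
refine_binary <- function(binary, config = refine_config()) {
  iseg <- extract_components(binary, config$connectivity)
  iseg <- filter_candidates(iseg, config)
  if (config$split) {
    iseg <- split_fused(iseg, config)
    iseg <- filter_candidates(iseg, config)
  }
  iseg
}

instance_mask <- function(iseg, id) iseg$labels == id

`%||%` <- function(a, b) if (is.null(a)) b else a
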