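#' Specify simulated network-failure corruptions
#'
#' Turns a ground-truth phantom into the pair of hard labelmaps a
#' segmentation network would emit, with controllable failure modes:
#' instance fusion (a bone bridge across the disc gap, the failure the
#' watershed must repair), boundary erosion/dilation, per-instance level
#' mislabeling (the failure that breaks label propagation), spurious small
#' islands, and per-instance voxel dropout.
#'
#' @param fuse_pairs List of length-2 integer vectors of *adjacent* instance
#'   ids to connect, e.g. `list(c(2, 3))`.
#' @param bridge_radius_mm Radius of the fusion bridge cylinder, mm.
#' @param boundary_noise_mm Magnitude bound of per-instance morphological
#'   perturbation: each instance is dilated or eroded by a radius drawn
#'   uniformly from `[-boundary_noise_mm, boundary_noise_mm]` (negative =
#'   erosion). Sub-voxel radii leave a hard labelmap unchanged.
#' @param mislabel List of entries `list(instance =, level =, fraction =)`:
#'   the most superior `fraction` of the instance's voxels are relabeled to
#'   `level` (name or code) in the level-coded output.
#' @param n_islands Number of spurious small foreground islands to add.
#' @param island_radius_mm Length-2 range of island radii, mm.
#' @param dropout_fraction Fraction of each instance's voxels removed as a
#'   contiguous slab from a random side (in \[0, 1)).
#' @param seed Integer seed for all corruption randomness.
#' @return A `corruption_spec` list.
#' @export
corruption_spec <- function(fuse_pairs = list(), bridge_radius_mm = 3,
                            boundary_noise_mm = 0, mislabel = list(),
                            n_islands = 0, island_radius_mm = c(2, 4),
                            dropout_fraction = 0, seed = 1) {
  for (p in fuse_pairs) {
    if (length(p) != 2L || abs(diff(as.integer(p))) != 1L) {
      stop("fuse_pairs entries must be adjacent instance id pairs")
    }
  }
  for (m in mislabel) {
    if (is.null(m$instance) || is.null(m$level) || is.null(m$fraction)) {
      stop("mislabel entries need $instance, $level, $fraction")
    }
    if (m$fraction < 0 || m$fraction > 1) stop("mislabel fraction must be in [0, 1]")
  }
  stopifnot(bridge_radius_mm > 0, boundary_noise_mm >= 0,
            n_islands >= 0, dropout_fraction >= 0, dropout_fraction < 1)
  structure(list(
    fuse_pairs = lapply(fuse_pairs, as.integer),
    bridge_radius_mm = bridge_radius_mm,
    boundary_noise_mm = boundary_noise_mm,
    mislabel = mislabel, n_islands = as.integer(n_islands),
    island_radius_mm = as.numeric(island_radius_mm),
    dropout_fraction = dropout_fraction, seed = as.integer(seed)
  ), class = "corruption_spec")
}

#' Simulate network predictions from a ground-truth phantom
#'
#' Applies a [corruption_spec()] to a ground-truth instance labelmap and its
#' level table, producing the two inputs of the downstream workflow: a
#' binary segmentation (as from the binary network) and a level-coded
#' segmentation (as from the labeling network). An empty spec returns the
#' uncorrupted foreground and level coding. Seeded and reproducible.
#'
#' @param gt Instance-coded [labelmap3d()] (ground truth).
#' @param levels Instance-to-level tibble as returned by [generate_phantom()].
#' @param cspec A [corruption_spec()].
#' @return List with `binary` and `level` [labelmap3d()] objects.
#' @export
corrupt_prediction <- function(gt, levels, cspec) {
  stopifnot(inherits(gt, "labelmap3d"), gt$semantics == "instance",
            inherits(cspec, "corruption_spec"))
  ids <- levels$instance_id
  for (p in cspec$fuse_pairs) {
    if (!all(p %in% ids)) stop("fuse_pairs references missing instance(s)")
  }
  withr::with_seed(cspec$seed, corrupt_prediction_impl(gt, levels, cspec))
}

corrupt_prediction_impl <- function(gt, levels, cspec) {
  d <- dim(gt$values)
  sp <- gt$spacing
  inst <- gt$values
  lvl_of <- integer(max(levels$instance_id))
  lvl_of[levels$instance_id] <- levels$level_code
  code <- array(0L, d)
  fg <- inst > 0L
  code[fg] <- lvl_of[inst[fg]]

  # 1) dropout: remove a contiguous slab from a random side of each instance
  if (cspec$dropout_fraction > 0) {
    for (i in levels$instance_id) {
      w <- which(inst == i)
      if (!length(w)) next
      axis <- sample.int(3L, 1L)
      from_low <- stats::runif(1) < 0.5
      coord <- arrayInd(w, d)[, axis]
      k <- floor(cspec$dropout_fraction * length(w))
      if (k < 1L) next
      ord <- order(coord, w, decreasing = !from_low)
      drop_idx <- w[ord[seq_len(k)]]
      inst[drop_idx] <- 0L
      code[drop_idx] <- 0L
    }
  }

  # 2) boundary noise: per-instance EDT-threshold dilation/erosion
  if (cspec$boundary_noise_mm > 0) {
    for (i in levels$instance_id) {
      r <- stats::runif(1, -cspec$boundary_noise_mm, cspec$boundary_noise_mm)
      m <- inst == i
      if (!any(m)) next
      if (r >= 0) {
        dist_to <- array(edt_to_set_cpp(m, d, sp), d)
        add <- dist_to <= r & inst == 0L
        inst[add] <- i
        code[add] <- lvl_of[i]
      } else {
        interior <- array(edt_to_set_cpp(!m, d, sp), d)
        rem <- m & interior <= -r
        inst[rem] <- 0L
        code[rem] <- 0L
      }
    }
  }

  # 3) fusion bridges across the disc gap (superior member's level)
  centroids <- instance_centroids(inst, sp, levels$instance_id)
  for (p in cspec$fuse_pairs) {
    sup <- min(p); inf <- max(p)  # smaller id = more superior
    cs <- centroids[[sup]]; ci <- centroids[[inf]]
    if (is.null(cs) || is.null(ci)) stop("fuse_pairs references an empty instance")
    cx <- (cs[1] + ci[1]) / 2; cy <- (cs[2] + ci[2]) / 2
    zr <- range(cs[3], ci[3])
    xs <- axis_coords(d[1], sp[1]); ys <- axis_coords(d[2], sp[2])
    zs <- axis_coords(d[3], sp[3])
    in_xy <- outer((xs - cx)^2, (ys - cy)^2, `+`) <= cspec$bridge_radius_mm^2
    in_z <- zs >= zr[1] & zs <= zr[2]
    cyl <- array(FALSE, d)
    cyl[, , in_z] <- in_xy
    add <- cyl & inst == 0L
    inst[add] <- sup
    code[add] <- lvl_of[sup]
  }

  # 4) mislabeling: superior slab of the instance gets the substitute level
  for (m in cspec$mislabel) {
    i <- as.integer(m$instance)
    new_code <- if (is.character(m$level)) level_code(m$level) else as.integer(m$level)
    w <- which(inst == i)
    if (!length(w)) next
    k <- round(m$fraction * length(w))
    if (k < 1L) next
    z <- arrayInd(w, d)[, 3]
    ord <- order(z, w, decreasing = TRUE)  # superior voxels first
    code[w[ord[seq_len(k)]]] <- new_code
  }

  # 5) spurious islands (random sphere, random level)
  if (cspec$n_islands > 0) {
    extent <- (d - 1) * sp
    for (s in seq_len(cspec$n_islands)) {
      ctr <- stats::runif(3, 0, extent)
      rad <- stats::runif(1, cspec$island_radius_mm[1], cspec$island_radius_mm[2])
      lv <- sample.int(17L, 1L)
      tmp <- array(0L, d)
      tmp <- paint_superellipsoid(tmp, ctr, rep(rad, 3), 2, sp, 1L)
      add <- tmp > 0L & inst == 0L
      inst[add] <- -1L  # island marker, foreground but no true instance
      code[add] <- lv
    }
  }

  binary <- array(0L, d)
  binary[inst != 0L] <- 1L
  list(
    binary = labelmap3d(binary, spacing = sp, origin = gt$origin, semantics = "binary"),
    level = labelmap3d(code, spacing = sp, origin = gt$origin, semantics = "level")
  )
}

instance_centroids <- function(inst, sp, ids) {
  out <- vector("list", max(ids))
  for (i in ids) {
    w <- which(inst == i)
    if (!length(w)) next
    ind <- arrayInd(w, dim(inst))
    out[[i]] <- c(mean(ind[, 1] - 1) * sp[1], mean(ind[, 2] - 1) * sp[2],
                  mean(ind[, 3] - 1) * sp[3])
  }
  out
}
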