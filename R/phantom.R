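#' Specify a synthetic thoracolumbar spine phantom
#'
#' Phantoms emulate the study regime the workflow targets: a craniocaudal
#' stack of at least five vertebral-body-like blobs separated by disc gaps,
#' optionally truncated at the volume edges. Bodies are superellipsoids
#' (rounded squat boxes, exponent `superellipse_power`) because watershed
#' behavior depends on the blobs being body-shaped rather than spherical.
#' Instance ids run 1..n from cranial (most superior, assigned
#' `first_level`) to caudal.
#'
#' @param n_vertebrae Number of vertebral bodies (>= 1).
#' @param first_level Level of the most superior body ("T1".."L5" or code).
#' @param body_radius_mm Semi-axes (right-left, anterior-posterior,
#'   craniocaudal) of each body, mm. Defaults give a 28 x 24 x 26 mm body
#'   of ~14 cm^3, a realistic adult vertebral body.
#' @param disc_gap_mm Craniocaudal gap between consecutive bodies, mm.
#' @param spacing_mm Voxel size, mm (default 1 mm isotropic, the working
#'   resolution of the pipeline).
#' @param volume_shape Grid shape; `NULL` = computed to fit the stack plus
#'   `margin_mm`.
#' @param margin_mm Soft-tissue margin around the stack, mm.
#' @param lateral_jitter_mm Amplitude bound of a smooth sinusoidal lateral
#'   displacement of body centers (mild scoliosis-like curvature), mm.
#' @param noise_sd Gaussian intensity noise s.d. (HU-like units).
#' @param partial_at_edges If `TRUE`, the stack is shifted so the most
#'   superior body is truncated by the volume face (partially visible
#'   vertebra).
#' @param superellipse_power Superellipsoid exponent (2 = ellipsoid).
#' @param seed Integer seed; all phantom randomness flows from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_vertebrae = 5, first_level = "T9",
                         body_radius_mm = c(14, 12, 13), disc_gap_mm = 4,
                         spacing_mm = c(1, 1, 1), volume_shape = NULL,
                         margin_mm = 8, lateral_jitter_mm = 2, noise_sd = 15,
                         partial_at_edges = FALSE, superellipse_power = 4,
                         seed = 1) {
  n <- as.integer(n_vertebrae)
  if (n < 1L) stop("n_vertebrae must be >= 1")
  first_code <- if (is.character(first_level)) level_code(first_level) else as.integer(first_level)
  if (first_code < 1L || first_code > 17L) stop("first_level out of T1..L5")
  if (n > n_levels_from(first_code)) {
    stop("n_vertebrae = ", n, " runs past L5 when starting at ",
         level_name(first_code))
  }
  stopifnot(length(body_radius_mm) == 3L, all(body_radius_mm > 0),
            disc_gap_mm > 0, all(spacing_mm > 0), superellipse_power >= 2)
  structure(list(
    n_vertebrae = n, first_code = first_code,
    body_radius_mm = as.numeric(body_radius_mm),
    disc_gap_mm = disc_gap_mm, spacing_mm = as.numeric(spacing_mm),
    volume_shape = volume_shape, margin_mm = margin_mm,
    lateral_jitter_mm = lateral_jitter_mm, noise_sd = noise_sd,
    partial_at_edges = isTRUE(partial_at_edges),
    superellipse_power = superellipse_power, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# physical coordinate of 1-based voxel index along one axis
axis_coords <- function(n, sp) (seq_len(n) - 1) * sp

# Paint a superellipsoid into an integer instance array; returns the array.
paint_superellipsoid <- function(arr, center, radii, power, spacing, value) {
  d <- dim(arr)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor((center[a] - radii[a]) / spacing[a]) + 1L)
    hi <- min(d[a], ceiling((center[a] + radii[a]) / spacing[a]) + 1L)
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0L)) return(arr)
  cx <- (rng[[1]] - 1) * spacing[1] - center[1]
  cy <- (rng[[2]] - 1) * spacing[2] - center[2]
  cz <- (rng[[3]] - 1) * spacing[3] - center[3]
  p <- power
  fx <- abs(cx / radii[1])^p
  fy <- abs(cy / radii[2])^p
  fz <- abs(cz / radii[3])^p
  inside <- outer(outer(fx, fy, `+`), fz, `+`) <= 1
  sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub[inside] <- value
  arr[rng[[1]], rng[[2]], rng[[3]]] <- sub
  arr
}

#' Generate a seeded spine phantom
#'
#' Produces a CT-like intensity volume (soft-tissue background, trabecular
#' interior, brighter cortical shell, Gaussian noise), a ground-truth
#' instance labelmap, and the instance-to-level table. Identical spec and
#' seed give bit-identical outputs.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` ([volume3d()]), `instances`
#'   (instance-coded [labelmap3d()]), and `levels` (tibble: `instance_id`,
#'   `level_code`, `level_name`, `edge_contact`, `n_voxels`).
#' @examples
#' ph <- generate_phantom(phantom_spec(n_vertebrae = 3, seed = 7))
#' ph$levels
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  r <- spec$body_radius_mm
  sp <- spec$spacing_mm
  n <- spec$n_vertebrae
  pitch <- 2 * r[3] + spec$disc_gap_mm
  stack_len <- n * 2 * r[3] + (n - 1) * spec$disc_gap_mm

  d <- spec$volume_shape
  if (is.null(d)) {
    d <- c(
      ceiling((2 * r[1] + 2 * (spec$margin_mm + spec$lateral_jitter_mm)) / sp[1]),
      ceiling((2 * r[2] + 2 * (spec$margin_mm + spec$lateral_jitter_mm)) / sp[2]),
      ceiling((stack_len + 2 * spec$margin_mm) / sp[3])
    )
  }
  d <- as.integer(d)
  extent <- (d - 1) * sp  # physical coordinate of the last voxel

  # body centers, cranial (i = 1) to caudal
  z_top <- extent[3] - spec$margin_mm - r[3]
  # truncation regime: the top body's center sits half a body height above
  # the superior face, leaving only a sub-minimum cap visible
  if (spec$partial_at_edges) z_top <- z_top + spec$margin_mm + 1.5 * r[3]
  zc <- z_top - (seq_len(n) - 1) * pitch
  amp <- stats::runif(2, 0, spec$lateral_jitter_mm)
  phase <- stats::runif(2, 0, 2 * pi)
  xc <- extent[1] / 2 + amp[1] * sin(2 * pi * seq_len(n) / max(n, 2) + phase[1])
  yc <- extent[2] / 2 + amp[2] * sin(2 * pi * seq_len(n) / max(n, 2) + phase[2])

  inst <- array(0L, d)
  for (i in seq_len(n)) {
    inst <- paint_superellipsoid(inst, c(xc[i], yc[i], zc[i]), r,
                                 spec$superellipse_power, sp, i)
  }
  counts <- tabulate(inst[inst > 0L], nbins = n)
  if (any(counts == 0L)) {
    stop("Phantom bodies cannot fit the volume: instance(s) ",
         paste(which(counts == 0L), collapse = ", "), " have no voxels")
  }

  edge <- vapply(seq_len(n), function(i) {
    w <- which(inst == i, arr.ind = TRUE)
    any(w == 1L) || any(sweep(w, 2, d, `==`))
  }, logical(1))

  # intensity model: soft tissue 40, trabecular 200, cortical shell 700 (HU)
  mask <- inst > 0L
  surf <- surface_mask(mask)
  vol <- array(40, d)
  vol[mask] <- 200
  vol[surf] <- 700
  vol <- vol + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)

  levels <- tibble::tibble(
    instance_id = seq_len(n),
    level_code = spec$first_code + seq_len(n) - 1L,
    level_name = level_name(spec$first_code + seq_len(n) - 1L),
    edge_contact = edge,
    n_voxels = as.integer(counts)
  )
  list(
    volume = volume3d(vol, spacing = sp),
    instances = labelmap3d(inst, spacing = sp, semantics = "instance"),
    levels = levels
  )
}

# Foreground voxels with at least one 6-neighbor outside the foreground
# (voxels on the grid boundary count as surface).
surface_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_all_inside <- function(m, axis, by) {
    # TRUE where the neighbor at offset `by` along `axis` exists and is TRUE
    out <- array(FALSE, dim(m))
    idx_to <- lapply(dim(m), seq_len)
    idx_from <- idx_to
    n <- dim(m)[axis]
    if (by > 0) { idx_to[[axis]] <- seq_len(n - by); idx_from[[axis]] <- (1 + by):n }
    else { idx_to[[axis]] <- (1 - by):n; idx_from[[axis]] <- seq_len(n + by) }
    out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      m[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    interior <- interior & shift_all_inside(mask, axis, by)
  }
  mask & !interior
}
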