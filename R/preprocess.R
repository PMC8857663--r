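#' Resample a volume or labelmap to isotropic voxels
#'
#' Resamples to a cubic voxel of `target_spacing_mm` (default 1 mm, the
#' resolution the downstream refinement assumes). The output shape is
#' `ceiling(dim * spacing / target)` per axis under a voxel-center
#' convention with shared origin. Intensity volumes are interpolated
#' trilinearly; labelmaps use nearest-neighbor so label values are never
#' blended.
#'
#' @param x A [volume3d()] or [labelmap3d()].
#' @param target_spacing_mm Positive scalar, output voxel size in mm.
#' @return Object of the same class as `x` at the new spacing.
#' @examples
#' lm <- labelmap3d(array(0L, c(10, 10, 5)), spacing = c(0.8, 0.8, 2))
#' dim(resample_isotropic(lm, 1)$values)  # 8 x 8 x 10
#' @export
resample_isotropic <- function(x, target_spacing_mm = 1) {
  stopifnot(inherits(x, "volume3d") || inherits(x, "labelmap3d"))
  t <- target_spacing_mm
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("`target_spacing_mm` must be a positive scalar")
  }
  d <- dim(x$values)
  if (isTRUE(all.equal(x$spacing, rep(t, 3), tolerance = 1e-10))) {
    return(x)
  }
  odim <- as.integer(ceiling(d * x$spacing / t))
  odim <- pmax(odim, 1L)
  nearest <- inherits(x, "labelmap3d")
  out <- resample_grid_cpp(as.numeric(x$values), as.integer(d),
                           as.numeric(x$spacing), odim, t, nearest)
  arr <- array(out, odim)
  if (nearest) {
    labelmap3d(arr, spacing = rep(t, 3), origin = x$origin,
               semantics = x$semantics)
  } else {
    volume3d(arr, spacing = rep(t, 3), origin = x$origin)
  }
}

#' Window-normalize CT intensities
#'
#' Affine intensity normalization used before network inference: the window
#' `[window_low, window_high]` (Hounsfield units) is mapped linearly onto
#' [-0.5, 1.5] and values outside the window are clipped to those bounds.
#' The default window (-1000, 1000) HU spans air to dense bone.
#'
#' @param v A [volume3d()].
#' @param window_low,window_high Window bounds in HU, `window_low < window_high`.
#' @return A [volume3d()] with values in [-0.5, 1.5].
#' @examples
#' v <- volume3d(array(c(-1000, 0, 1000, 2000), c(4, 1, 1)))
#' normalize_intensity(v)$values[, 1, 1]  # -0.5 0.5 1.5 1.5
#' @export
normalize_intensity <- function(v, window_low = -1000, window_high = 1000) {
  stopifnot(inherits(v, "volume3d"))
  if (!is.finite(window_low) || !is.finite(window_high) ||
      window_low >= window_high) {
    stop("Degenerate window: need window_low < window_high")
  }
  scaled <- -0.5 + 2 * (v$values - window_low) / (window_high - window_low)
  scaled[scaled < -0.5] <- -0.5
  scaled[scaled > 1.5] <- 1.5
  volume3d(scaled, spacing = v$spacing, origin = v$origin)
}
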