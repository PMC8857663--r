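#' Dice similarity coefficient of two voxel sets
#'
#' `2|A∩B| / (|A|+|B|)`; defined as 1 when both sets are empty. Accepts
#' logical arrays on the same grid.
#'
#' @param a,b Logical 3-D arrays of identical shape.
#' @return Fraction in \[0, 1\].
#' @examples
#' a <- array(FALSE, c(3, 3, 3)); a[1:2, , ] <- TRUE
#' dice(a, a)
#' @export
dice <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b))
  if (!identical(dim(a), dim(b))) stop("Grids are misaligned: shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Hausdorff distance between two voxel sets
#'
#' The classical maximum Hausdorff distance over surface voxels (foreground
#' voxels with at least one background 6-neighbor; grid-boundary voxels
#' count as surface), in mm using the physical voxel spacing. The
#' `percentile` argument selects the robust percentile variant (e.g. 95);
#' the default 100 is the classical maximum.
#'
#' @param a,b Non-empty logical 3-D arrays of identical shape.
#' @param spacing Voxel size in mm (length 3).
#' @param percentile Percentile of the directed surface distances, in
#'   (0, 100\]; 100 = maximum.
#' @return Distance in mm.
#' @examples
#' a <- array(FALSE, c(5, 5, 5)); a[2, 2, 2] <- TRUE
#' b <- array(FALSE, c(5, 5, 5)); b[2, 2, 5] <- TRUE
#' hausdorff(a, b)  # 3 mm
#' @export
hausdorff <- function(a, b, spacing = c(1, 1, 1), percentile = 100) {
  stopifnot(is.logical(a), is.logical(b))
  if (!identical(dim(a), dim(b))) stop("Grids are misaligned: shapes differ")
  if (!any(a) || !any(b)) {
    stop("Hausdorff distance is undefined for an empty set")
  }
  stopifnot(percentile > 0, percentile <= 100)
  # surfaces are computed on the full grid, then distances on the joint
  # bounding box (padded); cropping after surface extraction is exact
  sa <- surface_mask(a)
  sb <- surface_mask(b)
  ind <- arrayInd(which(a | b), dim(a))
  lo <- pmax(apply(ind, 2, min) - 1L, 1L)
  hi <- pmin(apply(ind, 2, max) + 1L, dim(a))
  sa <- sa[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sb <- sb[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(sa)
  dist_to_b <- array(edt_to_set_cpp(sb, as.integer(d), as.numeric(spacing)), d)
  dist_to_a <- array(edt_to_set_cpp(sa, as.integer(d), as.numeric(spacing)), d)
  dab <- dist_to_b[sa]
  dba <- dist_to_a[sb]
  if (percentile == 100) {
    max(max(dab), max(dba))
  } else {
    max(stats::quantile(dab, percentile / 100, names = FALSE),
        stats::quantile(dba, percentile / 100, names = FALSE))
  }
}
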