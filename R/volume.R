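#' 3-D volume and labelmap containers
#'
#' A `volume3d` holds a 3-D scalar grid (CT-like intensities) together with
#' its physical voxel spacing in mm and the physical position of voxel
#' (1,1,1) (`origin`, mm). A `labelmap3d` is the integer-valued counterpart
#' with a declared semantics: `"binary"` (values 0/1), `"level"` (0..17,
#' the thoracolumbar code table of [vertebra_levels()]) or `"instance"`
#' (0 = background, positive integers = instance ids).
#'
#' Axis convention: axis 3 (the last, slowest-varying array axis) is the
#' craniocaudal axis with increasing index = superior. Images must be
#' reoriented to this convention on load; the package performs no implicit
#' reorientation beyond trusting the NIfTI header spacing.
#'
#' @param values 3-D numeric (volume) or integer-valued (labelmap) array.
#' @param spacing Numeric length-3, voxel size in mm, strictly positive.
#' @param origin Numeric length-3, physical position of the first voxel (mm).
#' @param semantics One of "binary", "level", "instance" for labelmaps.
#' @return An object of class `volume3d` or `labelmap3d`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v$values)
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid(values, spacing, origin)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @rdname volume3d
#' @export
labelmap3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       semantics = c("binary", "level", "instance")) {
  semantics <- match.arg(semantics)
  check_grid(values, spacing, origin)
  if (any(values %% 1 != 0) || any(values < 0)) {
    stop("Labelmap values must be non-negative integers")
  }
  storage.mode(values) <- "integer"
  if (semantics == "binary" && !all(values %in% c(0L, 1L))) {
    stop("Binary labelmap values must be 0 or 1")
  }
  if (semantics == "level" && any(values > 17L)) {
    stop("Level-coded labelmap values must lie in 0..17")
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), semantics = semantics),
            class = "labelmap3d")
}

check_grid <- function(values, spacing, origin) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive voxel sizes (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite coordinates (mm)")
  }
  invisible(TRUE)
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.labelmap3d <- function(x, ...) {
  cat("<labelmap3d:", x$semantics, "> ",
      paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", sum(x$values > 0L), " foreground voxels\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

stop_if_misaligned <- function(a, b) {
  if (!same_grid(a, b)) stop("Grids are misaligned: shapes/spacings differ")
  invisible(TRUE)
}

LEVEL_TABLE_DESCRIPTION <- "levels:0=bg,1-12=T1-T12,13-17=L1-L5"

#' Read and write volumes and labelmaps as NIfTI-1
#'
#' Thin wrappers around [RNifti] that attach spacing metadata and, for
#' labelmaps, validate integer content. Float-stored files whose values are
#' all integral are accepted and cast; any fractional value is an error for
#' a labelmap. Level-coded outputs carry the fixed code table
#' (0 = background, 1..12 = T1..T12, 13..17 = L1..L5) in the header
#' description field.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param semantics Labelmap semantics, see [labelmap3d()].
#' @return `read_volume()` a [volume3d()]; `read_labelmap()` a [labelmap3d()].
#' @export
read_labelmap <- function(path, semantics = c("binary", "level", "instance")) {
  semantics <- match.arg(semantics)
  if (!file.exists(path)) stop("File not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("Expected a 3-D NIfTI image: ", path)
  vals <- array(as.vector(img), dim(img))  # strip niftiImage attributes
  if (any(vals %% 1 != 0)) {
    stop("Labelmap contains non-integer values: ", path)
  }
  labelmap3d(vals, spacing = RNifti::pixdim(img)[1:3], semantics = semantics)
}

#' @rdname read_labelmap
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("Expected a 3-D NIfTI image: ", path)
  vals <- array(as.vector(img), dim(img))  # strip niftiImage attributes
  volume3d(vals, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_labelmap
#' @param x A [volume3d()] or [labelmap3d()].
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, "volume3d") || inherits(x, "labelmap3d"))
  is_lab <- inherits(x, "labelmap3d")
  ref <- if (is_lab && x$semantics == "level") {
    list(descrip = LEVEL_TABLE_DESCRIPTION)
  } else NULL
  img <- RNifti::asNifti(x$values, reference = ref)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = if (is_lab) "int16" else "float")
  invisible(path)
}
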