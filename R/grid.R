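#' Voxel grid with world-coordinate affine
#'
#' A voxel grid couples an array shape to a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in millimetres (RAS+ convention, as in NIfTI).
#' All rasterization, scoring and field computations in the package are
#' expressed on such grids, so that volumes in mL and distances in mm are
#' exact functions of the affine.
#'
#' @param dim integer vector of length 3, array shape.
#' @param voxel_mm voxel edge lengths in mm (length 1 or 3). Ignored when
#'   `affine` is given.
#' @param origin_mm world coordinates of the centre of voxel (0, 0, 0).
#'   Ignored when `affine` is given.
#' @param affine optional full 4x4 voxel-to-world transform.
#' @return An object of class `voxel_grid` with elements `dim` and `affine`.
#' @examples
#' g <- voxel_grid(c(64, 64, 48), voxel_mm = 1.5)
#' voxel_volume(g)
#' @export
voxel_grid <- function(dim, voxel_mm = 1, origin_mm = c(0, 0, 0), affine = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  if (is.null(affine)) {
    voxel_mm <- rep_len(voxel_mm, 3)
    stopifnot(all(voxel_mm > 0), length(origin_mm) == 3)
    affine <- diag(c(voxel_mm, 1))
    affine[1:3, 4] <- origin_mm
  }
  stopifnot(all(dim(as.matrix(affine)) == c(4, 4)))
  affine <- matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine[1:3, 1:3])) <= .Machine$double.eps)
    stop("affine must be invertible", call. = FALSE)
  structure(list(dim = dim, affine = affine), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dim, collapse = " x "),
      " voxels, voxel volume ", format(voxel_volume(x)), " mm^3\n", sep = "")
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param grid a [voxel_grid()].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) {
  abs(det(grid$affine[1:3, 1:3]))
}

#' World coordinates of all voxel centres
#'
#' @param grid a [voxel_grid()].
#' @return A list of three arrays (`x`, `y`, `z`), each of the grid's shape,
#'   holding world mm coordinates of voxel centres.
#' @export
voxel_coords <- function(grid) {
  d <- grid$dim
  A <- grid$affine
  i <- seq_len(d[1]) - 1
  j <- seq_len(d[2]) - 1
  k <- seq_len(d[3]) - 1
  # separable for a general affine: c(A %*% (i,j,k,1)) = col1*i + col2*j + col3*k + col4
  axis_term <- function(row) {
    outer(outer(A[row, 1] * i, A[row, 2] * j, `+`), A[row, 3] * k + A[row, 4], `+`)
  }
  list(x = axis_term(1), y = axis_term(2), z = axis_term(3))
}

#' Total volume of a logical mask in mL
#' @param mask logical or 0/1 array.
#' @param grid the [voxel_grid()] the mask lives on.
#' @return Volume in mL (1 mL = 1000 mm^3).
#' @export
mask_volume_mL <- function(mask, grid) {
  sum(mask != 0) * voxel_volume(grid) / 1000
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) && max(abs(a$affine - b$affine)) < tol
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " must share one voxel grid (shape and affine)", call. = FALSE)
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the package's `voxel_grid` affine in
#' the sform (code 2). `read_volume()` returns a plain array with a
#' `voxel_grid` attached as attribute `grid`.
#'
#' @param vol numeric, integer or logical array.
#' @param grid the [voxel_grid()] of `vol`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` an array
#'   with attribute `grid`.
#' @export
write_volume <- function(vol, grid, path) {
  stopifnot(all(dim(vol) == grid$dim))
  storage.mode(vol) <- if (is.logical(vol)) "integer" else storage.mode(vol)
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  attr(arr, "grid") <- voxel_grid(dim(arr), affine = aff)
  arr
}
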