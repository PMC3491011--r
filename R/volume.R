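#' @useDynLib gwtbss, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd var median quantile setNames pt
#' @importFrom utils combn head write.csv read.csv
NULL

#' Scalar FA volume
#'
#' The universal image container: a 3D numeric array of fractional-anisotropy
#' values with millimetre voxel spacing. World coordinates of voxel
#' `(i, j, k)` (1-based) are `(i - 1, j - 1, k - 1) * voxel_size` mm.
#'
#' @param data 3D numeric array (values typically in `[0, 1]` for FA).
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return An object of class `fa_volume`.
#' @export
fa_volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("fa_volume requires a 3D array, got ", length(dim(data)), " dims")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(data, voxel_size = as.numeric(voxel_size),
            class = c("fa_volume", "array"))
}

#' @export
print.fa_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fa_volume> %d x %d x %d voxels, %s mm, range [%.3f, %.3f]\n",
              d[1], d[2], d[3],
              paste(format(voxel_size(x)), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

#' Voxel size of a volume or field
#' @param x an `fa_volume`, `label_volume` or `disp_field`.
#' @return numeric length-3, mm.
#' @export
voxel_size <- function(x) attr(x, "voxel_size")

#' Integer label volume
#'
#' A 3D integer array of region/tract labels (0 = background) with voxel
#' spacing, used for tract masks.
#'
#' @param data 3D integer-valued array.
#' @inheritParams fa_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("label_volume requires a 3D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  storage.mode(data) <- "integer"
  structure(data, voxel_size = as.numeric(voxel_size),
            class = c("label_volume", "array"))
}

#' Dense displacement field
#'
#' Per-voxel 3-vector displacements in mm on a reference grid, stored as a
#' 4D array `[nx, ny, nz, 3]`. The convention throughout the package is
#' *pull-back*: resampling an image `v` through field `u` produces
#' `out(x) = v(x + u(x))`, with `x` in voxel units and `u` in mm.
#'
#' @param data 4D numeric array with last dimension 3 (mm units).
#' @inheritParams fa_volume
#' @return An object of class `disp_field`.
#' @export
disp_field <- function(data, voxel_size = c(1, 1, 1)) {
  d <- dim(data)
  if (length(d) != 4L || d[4] != 3L)
    stop("disp_field requires a 4D array with last dimension 3")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (!all(is.finite(data))) stop("displacement field must be finite everywhere")
  structure(data, voxel_size = as.numeric(voxel_size),
            class = c("disp_field", "array"))
}

#' Zero displacement field on a given grid
#' @param grid_shape integer length-3.
#' @inheritParams fa_volume
#' @export
zero_field <- function(grid_shape, voxel_size = c(1, 1, 1)) {
  disp_field(array(0, c(grid_shape, 3L)), voxel_size)
}

#' @export
print.disp_field <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<disp_field> %d x %d x %d grid, mean |u| = %.3f mm\n",
              d[1], d[2], d[3], deformation_magnitude(x)))
  invisible(x)
}

grid_shape <- function(x) dim(x)[1:3]

same_grid <- function(a, b) {
  identical(grid_shape(a), grid_shape(b)) &&
    isTRUE(all.equal(voxel_size(a), voxel_size(b)))
}

as_num3 <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x)[1:3])
  y
}

#' Root-mean-square error between two volumes
#' @param a,b volumes on the same grid.
#' @export
rmse <- function(a, b) {
  stopifnot(all(dim(a)[1:3] == dim(b)[1:3]))
  sqrt(mean((as.numeric(a) - as.numeric(b))^2))
}

#' Normalised cross-correlation between two volumes
#' @param a,b volumes on the same grid.
#' @export
ncc <- function(a, b) {
  stopifnot(all(dim(a)[1:3] == dim(b)[1:3]))
  c_ncc(as.numeric(a), as.numeric(b))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with reflection boundary handling; the kernel
#' width is given in mm and converted to voxels via the voxel size.
#'
#' @param volume an `fa_volume`.
#' @param sigma_mm Gaussian standard deviation in mm (scalar).
#' @export
gaussian_smooth <- function(volume, sigma_mm) {
  if (sigma_mm <= 0) return(volume)
  vs <- voxel_size(volume)
  out <- c_gauss3d(as.numeric(volume), dim(volume), sigma_mm / vs)
  fa_volume(array(out, dim(volume)), vs)
}
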