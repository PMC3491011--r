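#' Affine (or rigid) transform in world coordinates
#'
#' A 4x4 homogeneous matrix mapping world (mm) coordinates of the *fixed*
#' image to world coordinates of the *moving* image (pull-back convention:
#' `resample(moving, T)` produces the moving image aligned to the fixed one).
#'
#' @param matrix 4x4 numeric homogeneous matrix.
#' @param kind `"rigid"` or `"affine"`. Rigid transforms must have an
#'   orthonormal linear part with determinant +1 (tolerance 1e-6).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(4), kind = c("affine", "rigid")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix)) < 1e-12) stop("affine matrix is not invertible")
  if (kind == "rigid") {
    L <- matrix[1:3, 1:3]
    if (max(abs(crossprod(L) - diag(3))) > 1e-6 || abs(det(L) - 1) > 1e-6)
      stop("rigid transform requires an orthonormal linear part with det +1")
  }
  structure(list(matrix = matrix, kind = kind), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> kind = %s\n", x$kind))
  print(round(x$matrix, 4))
  invisible(x)
}

is_affine <- function(x) inherits(x, "affine_transform")
is_field <- function(x) inherits(x, "disp_field")

#' Invert an affine transform
#' @param transform an `affine_transform`.
#' @export
affine_inverse <- function(transform) {
  affine_transform(solve(transform$matrix), transform$kind)
}

## 0-based voxel coords of a grid as an N x 3 matrix (x fastest)
grid_coords0 <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cbind(rep.int(seq_len(nx) - 1L, ny * nz),
        rep.int(rep(seq_len(ny) - 1L, each = nx), nz),
        rep(seq_len(nz) - 1L, each = nx * ny))
}

## apply the pull-back map of a transform to 0-based voxel coords (N x 3),
## assuming source and target grids share `vs` voxel spacing
apply_map0 <- function(transform, pts0, vs, field_shape = NULL) {
  if (is_affine(transform)) {
    w <- sweep(pts0, 2, vs, "*")
    w2 <- w %*% t(transform$matrix[1:3, 1:3]) +
      matrix(transform$matrix[1:3, 4], nrow(pts0), 3, byrow = TRUE)
    sweep(w2, 2, vs, "/")
  } else if (is_field(transform)) {
    sh <- grid_shape(transform)
    u <- vapply(1:3, function(c.)
      c_sample_points(as.numeric(transform[, , , c.]), sh, pts0, 0L),
      numeric(nrow(pts0)))
    pts0 + sweep(u, 2, vs, "/")
  } else stop("unsupported transform type")
}

#' Resample a volume through a transform
#'
#' Pull-back resampling: each output voxel takes the interpolated value of
#' the input at its mapped source location; locations outside the input
#' field of view give 0.
#'
#' @param volume `fa_volume` or `label_volume`.
#' @param transform an `affine_transform`, a `disp_field`, or a list of
#'   transforms which is composed with [compose_transforms()] first.
#' @param interpolation `"trilinear"` or `"nearest"` (labels must use
#'   nearest).
#' @param reference optional volume or field defining the output grid;
#'   defaults to the transform's grid for fields, else the input grid.
#' @return A volume of the same class as `volume` on the output grid.
#' @export
resample <- function(volume, transform,
                     interpolation = c("trilinear", "nearest"),
                     reference = NULL) {
  interpolation <- match.arg(interpolation)
  mode <- if (interpolation == "trilinear") 0L else 1L
  if (is.list(transform) && !is_affine(transform))
    transform <- do.call(compose_transforms, transform)
  vs <- voxel_size(volume)
  if (!is.null(reference)) {
    oshape <- grid_shape(reference)
    ovs <- voxel_size(reference)
  } else if (is_field(transform)) {
    oshape <- grid_shape(transform); ovs <- voxel_size(transform)
  } else {
    oshape <- grid_shape(volume); ovs <- vs
  }
  src <- as.numeric(volume)
  sdim <- grid_shape(volume)
  if (is_affine(transform) && isTRUE(all.equal(ovs, vs))) {
    ## voxel-to-voxel 3x4 matrix for the fast path
    S <- diag(c(vs, 1)); M <- (solve(S) %*% transform$matrix %*% S)[1:3, ]
    out <- c_resample_affine(src, sdim, oshape, M, mode)
  } else if (is_field(transform) && identical(grid_shape(transform), oshape) &&
             isTRUE(all.equal(ovs, vs))) {
    out <- c_resample_field(src, sdim, as.numeric(transform), oshape, vs, mode)
  } else {
    pts <- apply_map0(transform, grid_coords0(oshape), ovs)
    ## map world coords of source into its own voxel units if spacings differ
    if (!isTRUE(all.equal(ovs, vs)))
      pts <- sweep(sweep(pts, 2, ovs, "*"), 2, vs, "/")
    out <- c_sample_points(src, sdim, pts, mode)
  }
  arr <- array(out, oshape)
  if (inherits(volume, "label_volume")) label_volume(arr, ovs)
  else fa_volume(arr, ovs)
}

#' Compose two transforms into a displacement field
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` to an image and then `a`: resampling through the result equals
#' `resample(resample(v, b), a)` up to interpolation error.
#'
#' @param a,b `affine_transform` or `disp_field` objects.
#' @param reference optional grid-defining object for the output field;
#'   defaults to `a`'s grid if `a` is a field, else `b`'s.
#' @return A `disp_field` on the reference grid.
#' @export
compose_transforms <- function(a, b, reference = NULL) {
  ref <- if (!is.null(reference)) reference
         else if (is_field(a)) a
         else if (is_field(b)) b
         else stop("composition of two affines needs a reference grid; ",
                   "multiply the matrices instead")
  shape <- grid_shape(ref); vs <- voxel_size(ref)
  x0 <- grid_coords0(shape)
  y <- apply_map0(a, x0, vs)
  z <- apply_map0(b, y, vs)
  u <- sweep(z - x0, 2, vs, "*")
  disp_field(array(u, c(shape, 3L)), vs)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `v` with `v(x) = -u(x + v(x))`, so that composing the result with
#' the input approximates the identity map.
#'
#' @param field a `disp_field`.
#' @param max_iter maximum fixed-point iterations.
#' @param tol_vox convergence tolerance on the mean update, in voxels.
#' @export
invert_field <- function(field, max_iter = 50, tol_vox = 0.05) {
  shape <- grid_shape(field); vs <- voxel_size(field)
  n <- prod(shape)
  u <- matrix(as.numeric(field), n, 3)
  x0 <- grid_coords0(shape)
  v <- -u
  mean_vs <- mean(vs)
  for (it in seq_len(max_iter)) {
    pts <- x0 + sweep(v, 2, vs, "/")
    u_at <- vapply(1:3, function(c.)
      c_sample_points(u[, c.], shape, pts, 0L), numeric(n))
    v_new <- -u_at
    delta <- mean(sqrt(rowSums((v_new - v)^2))) / mean_vs
    if (!is.finite(delta)) stop("field inversion diverged")
    v <- v_new
    if (delta < tol_vox) break
  }
  disp_field(array(v, c(shape, 3L)), vs)
}

#' Mean deformation magnitude of a field
#'
#' Mean over voxels of the Euclidean norm of the displacement, in mm.
#'
#' @param field a `disp_field`.
#' @export
deformation_magnitude <- function(field) {
  u <- matrix(as.numeric(field), ncol = 3)
  mean(sqrt(rowSums(u^2)))
}

#' Divergence of a displacement field
#'
#' Central-difference divergence (1/mm units) of a field, used to verify
#' expansion/contraction behaviour of simulated deformations.
#'
#' @param field a `disp_field`.
#' @return An `fa_volume`-shaped numeric array (not clamped).
#' @export
field_divergence <- function(field) {
  shape <- grid_shape(field); vs <- voxel_size(field)
  div <- array(0, shape)
  for (c. in 1:3) {
    g <- c_gradient(as.numeric(field[, , , c.]), shape, vs)
    div <- div + array(g[, c.], shape)
  }
  div
}
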