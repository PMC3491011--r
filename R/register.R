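## Registration: linear (rigid/affine, NCC), non-rigid (demons and
## coarse-grid parametric), multi-resolution pyramids.

## Gaussian-smoothed downsampling by an integer factor
downsample_volume <- function(volume, factor) {
  if (factor == 1) return(volume)
  vs <- voxel_size(volume)
  shape <- grid_shape(volume)
  sm <- c_gauss3d(as.numeric(volume), shape, rep(factor / 2, 3))
  oshape <- pmax(as.integer(ceiling(shape / factor)), 4L)
  M <- cbind(diag(3) * factor, rep(0, 3))
  out <- c_resample_affine(sm, shape, oshape, M, 0L)
  fa_volume(array(out, oshape), vs * factor)
}

## upsample a field from a coarse grid onto a fine grid (same world extent)
upsample_field <- function(field, fine_shape, fine_vs) {
  cshape <- grid_shape(field); cvs <- voxel_size(field)
  ratio <- fine_vs / cvs
  M <- cbind(diag(ratio), rep(0, 3))
  u <- vapply(1:3, function(c.)
    c_resample_affine(as.numeric(field[, , , c.]), cshape, fine_shape, M, 0L),
    numeric(prod(fine_shape)))
  disp_field(array(u, c(fine_shape, 3L)), fine_vs)
}

## build the pull-back affine matrix from a parameter vector
## p = (tx ty tz, rx ry rz [, log-scales sx sy sz, shears hxy hxz hyz])
params_to_affine <- function(p, centre_mm, kind) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx
  if (kind == "affine" && length(p) >= 12) {
    A <- A %*% diag(exp(p[7:9]))
    Sh <- diag(3); Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
    A <- A %*% Sh
  }
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- centre_mm - A %*% centre_mm + p[1:3]
  affine_transform(M, kind)
}

#' Linear (rigid or affine) registration
#'
#' Multi-resolution iterative optimisation of normalised cross-correlation
#' between the resampled moving image and the fixed image, over rigid
#' (translation + rotation) or full affine (+ scale + shear) parameters.
#' Deterministic: fixed identity initialisation, derivative-free simplex
#' search. The returned transform never has lower NCC than the identity
#' (attribute `converged` records optimiser status).
#'
#' @param moving,fixed `fa_volume`s with overlapping fields of view.
#' @param kind `"affine"` (default) or `"rigid"`.
#' @param levels integer pyramid downsampling factors, coarse to fine.
#' @param maxit simplex iterations per level (recycled).
#' @return An `affine_transform` (pull-back, fixed-world to moving-world).
#' @export
register_linear <- function(moving, fixed, kind = c("affine", "rigid"),
                            levels = c(4, 2), maxit = c(400, 150)) {
  kind <- match.arg(kind)
  npar <- if (kind == "rigid") 6L else 12L
  maxit <- rep(maxit, length.out = length(levels))
  centre <- (grid_shape(fixed) - 1) / 2 * voxel_size(fixed)
  p <- rep(0, npar)
  parscale_full <- c(rep(1, 3), rep(0.02, 3), rep(0.02, max(0, npar - 6)))
  conv <- TRUE
  for (li in seq_along(levels)) {
    f <- levels[li]
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    fxv <- as.numeric(fx)
    obj <- function(q) {
      tr <- params_to_affine(q, centre, kind)
      -c_ncc(as.numeric(resample(mv, tr, reference = fx)), fxv)
    }
    if (kind == "affine" && li == 1) {
      ## stage the search: rigid subset first, then the full affine set
      obj6 <- function(q6) obj(c(q6, rep(0, 3), rep(0, 3)))
      fit6 <- stats::optim(p[1:6], obj6, method = "Nelder-Mead",
                           control = list(maxit = maxit[li],
                                          parscale = parscale_full[1:6],
                                          reltol = 1e-7))
      p[1:6] <- fit6$par
    }
    fit <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[li],
                                       parscale = parscale_full[1:npar],
                                       reltol = 1e-7))
    p <- fit$par
  }
  tr <- params_to_affine(p, centre, kind)
  ## guarantee monotonicity of the returned solution at full resolution
  ncc_id <- c_ncc(as.numeric(moving), as.numeric(fixed))
  ncc_tr <- c_ncc(as.numeric(resample(moving, tr, reference = fixed)),
                  as.numeric(fixed))
  if (ncc_tr < ncc_id) {
    tr <- params_to_affine(rep(0, npar), centre, kind)
    conv <- FALSE
    warning("linear registration did not improve on the identity; ",
            "returning the identity transform")
  }
  attr(tr, "converged") <- conv
  tr
}

## demons non-rigid registration (non-parametric, intensity-driven)
register_demons <- function(moving, fixed, levels = c(4, 2, 1),
                            iters = c(40, 30, 12),
                            sigma_fluid_mm = NULL, sigma_elastic_mm = NULL,
                            max_step_mm = NULL) {
  vs <- voxel_size(fixed)
  if (is.null(sigma_fluid_mm)) sigma_fluid_mm <- 0.75 * mean(vs)
  if (is.null(sigma_elastic_mm)) sigma_elastic_mm <- 0.5 * mean(vs)
  if (is.null(max_step_mm)) max_step_mm <- 0.6 * mean(vs)
  iters <- rep(iters, length.out = length(levels))
  field <- NULL
  for (li in seq_along(levels)) {
    f <- levels[li]
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    shp <- grid_shape(fx); lvs <- voxel_size(fx)
    init <- if (is.null(field)) zero_field(shp, lvs)
            else upsample_field(field, shp, lvs)
    u <- c_demons(as.numeric(fx), as.numeric(mv), shp, lvs,
                  as.numeric(init), iters[li],
                  sigma_fluid_mm, sigma_elastic_mm, max_step_mm)
    field <- disp_field(array(u, c(shp, 3L)), lvs)
  }
  field
}

## coarse-control-grid parametric non-rigid registration: the displacement
## field is the trilinear interpolation of a control-point lattice, fitted
## by gradient descent on SSD with backtracking
register_ffd <- function(moving, fixed, levels = c(2, 1),
                         spacing_vox = c(4, 2), iters = c(60, 60),
                         step_mm = 1.0, max_step_mm = NULL) {
  field <- NULL
  iters <- rep(iters, length.out = length(levels))
  spacing_vox <- rep(spacing_vox, length.out = length(levels))
  if (is.null(max_step_mm)) max_step_mm <- 0.6 * mean(voxel_size(fixed))
  for (li in seq_along(levels)) {
    f <- levels[li]
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    shp <- grid_shape(fx); lvs <- voxel_size(fx)
    sp <- as.integer(spacing_vox[li])
    ncp <- as.integer((shp - 1) %/% sp + 2L)
    cp0 <- matrix(0, prod(ncp), 3)
    if (!is.null(field)) {
      ## initialise from the previous level's field, sampled at the
      ## control-point locations
      prev <- upsample_field(field, shp, lvs)
      cpts <- grid_coords0(ncp) * sp
      for (c. in 1:3)
        cp0[, c.] <- c_sample_points(as.numeric(prev[, , , c.]), shp, cpts,
                                     0L)
    }
    res <- c_ffd(as.numeric(fx), as.numeric(mv), shp, lvs, sp, iters[li],
                 step_mm, max_step_mm, cp0)
    field <- disp_field(array(res$field, c(shp, 3L)), lvs)
  }
  field
}

#' Non-rigid registration
#'
#' Two deliberately distinct deformable-registration algorithms behind one
#' contract, so that simulation warps and pipeline registration never share
#' a deformation model: `"pipeline"` is parametric (a coarse control-point
#' lattice interpolated to a dense field, refined multi-resolution, SSD
#' loss), `"independent"` is non-parametric demons (intensity-difference
#' force field with Gaussian fluid/elastic regularisation). Both reduce the
#' mean squared intensity difference relative to the linearly aligned
#' baseline; inputs are expected to be pre-aligned linearly.
#'
#' @param moving,fixed `fa_volume`s on the same grid.
#' @param algorithm `"pipeline"` or `"independent"`.
#' @param ... passed to the underlying algorithm (levels, iterations, ...).
#' @return A `disp_field` on the fixed grid (pull-back).
#' @export
register_nonrigid <- function(moving, fixed,
                              algorithm = c("pipeline", "independent"),
                              ...) {
  algorithm <- match.arg(algorithm)
  if (!identical(grid_shape(moving), grid_shape(fixed)))
    stop("moving and fixed images must share a grid; shapes ",
         paste(grid_shape(moving), collapse = "x"), " vs ",
         paste(grid_shape(fixed), collapse = "x"))
  field <- if (algorithm == "pipeline") register_ffd(moving, fixed, ...)
           else register_demons(moving, fixed, ...)
  ## never return a field worse (in SSD) than the zero field
  ssd0 <- mean((as.numeric(moving) - as.numeric(fixed))^2)
  ssd1 <- mean((as.numeric(resample(moving, field)) - as.numeric(fixed))^2)
  if (ssd1 > ssd0) field <- zero_field(grid_shape(fixed), voxel_size(fixed))
  field
}

#' Interpolation-matched smoothing-kernel selection
#'
#' For each candidate width, smooths every original image with a Gaussian of
#' that width and computes the RMSE against the corresponding inverse-warped
#' image; returns the width minimising the average RMSE (ties broken toward
#' the smaller width). This matches the smoothing level induced by
#' interpolation during warping, so that a comparison of smoothed originals
#' with warped images does not detect interpolation blur itself.
#'
#' @param originals list of `fa_volume`s.
#' @param warped_back list of the same images after a warp and inverse-warp
#'   round trip (same length and order).
#' @param candidate_sigmas_mm numeric vector of candidate widths, mm.
#' @return The selected width (scalar), with the per-candidate mean RMSE
#'   table as attribute `rmse_table`.
#' @export
select_kernel_width <- function(originals, warped_back,
                                candidate_sigmas_mm = c(0.5, 1, 1.5, 2)) {
  if (length(candidate_sigmas_mm) < 1) stop("candidate set must be non-empty")
  if (length(originals) != length(warped_back))
    stop("originals and warped_back must have equal length (",
         length(originals), " vs ", length(warped_back), ")")
  tab <- vapply(candidate_sigmas_mm, function(s)
    mean(vapply(seq_along(originals), function(i)
      rmse(gaussian_smooth(originals[[i]], s), warped_back[[i]]),
      numeric(1))), numeric(1))
  names(tab) <- candidate_sigmas_mm
  ord <- order(tab, candidate_sigmas_mm)   # ties -> smaller sigma
  structure(candidate_sigmas_mm[ord[1]], rmse_table = tab)
}
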