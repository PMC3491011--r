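#' Synthetic FA template with known tract geometry
#'
#' Builds the phantom that plays the role of a standard-space FA template
#' plus tract label atlas: curved white-matter-like tubes with a Gaussian FA
#' cross-profile over a low-FA background, and one central low-FA
#' (CSF-like) ventricle region. Tube peaks exceed 0.6 and the profile decays
#' below 0.2 at the labelled tube boundary, so an FA > 0.2 skeleton
#' threshold separates tract cores from background.
#'
#' Centrelines are defined as the per-slice FA maximum within each tract's
#' perpendicular cross-section, so every centreline voxel carries the
#' maximum FA of its cross-section by construction.
#'
#' @param grid_shape integer length-3, at least 32 per axis.
#' @param voxel_size_mm voxel edge length(s) in mm.
#' @param n_tracts number of synthetic tracts (>= 1).
#' @param seed RNG seed; the template is deterministic given the seed.
#' @return A `phantom_template`: list with `fa` (`fa_volume`), `labels`
#'   (`label_volume`, 0 = background), `centrelines` (list of n x 3 matrices
#'   of 1-based voxel coordinates, ordered along the tract), `ventricle`
#'   (logical array), and the tube geometry parameters.
#' @export
make_template <- function(grid_shape = c(48, 48, 48), voxel_size_mm = 2,
                          n_tracts = 3, seed = 1) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (any(grid_shape < 32))
    stop("grid_shape must be at least 32 voxels per axis (got ",
         paste(grid_shape, collapse = "x"), ")")
  if (n_tracts < 1) stop("n_tracts must be >= 1")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]

  sigma_vox <- 2.0            # tube Gaussian cross-profile SD, voxels
  radius_vox <- 2.2 * sigma_vox  # labelled tube boundary
  lane <- nx / (n_tracts + 1)
  if (lane < 2 * radius_vox + 2)
    stop("grid too small to contain ", n_tracts,
         " tracts: lane spacing ", round(lane, 1),
         " voxels < required ", round(2 * radius_vox + 2, 1))

  set.seed(seed)
  bg <- 0.11
  peak <- stats::runif(n_tracts, 0.70, 0.80)
  amp_x <- stats::runif(n_tracts, 1.0, 2.0)   # curve amplitudes, voxels
  amp_z <- stats::runif(n_tracts, 0.8, 1.5)
  ph_x <- stats::runif(n_tracts, 0, 2 * pi)
  ph_z <- stats::runif(n_tracts, 0, 2 * pi)
  cyc <- sample(1:2, n_tracts, replace = TRUE)

  margin <- as.integer(ceiling(0.19 * ny))
  ys <- (margin + 1L):(ny - margin)
  cx <- lane * seq_len(n_tracts)
  cz <- rep(0.62 * nz, n_tracts)
  ## continuous centreline coordinates (1-based voxel units), per tract
  curve_x <- vapply(seq_len(n_tracts), function(t)
    cx[t] + amp_x[t] * sin(2 * pi * cyc[t] * (ys - 1) / ny + ph_x[t]),
    numeric(length(ys)))
  curve_z <- vapply(seq_len(n_tracts), function(t)
    cz[t] + amp_z[t] * sin(2 * pi * cyc[t] * (ys - 1) / ny + ph_z[t]),
    numeric(length(ys)))

  fa <- array(bg, grid_shape)
  labels <- array(0L, grid_shape)
  xs <- seq_len(nx); zs <- seq_len(nz)
  Xg <- matrix(xs, nx, nz)
  Zg <- matrix(zs, nx, nz, byrow = TRUE)
  ## smooth axial taper so tubes fade out instead of ending abruptly
  taper <- 5
  L <- length(ys)
  ramp <- pmin(1, seq_len(L) / taper, (L + 1 - seq_len(L)) / taper)
  env <- ramp^2 * (3 - 2 * ramp)
  core <- env >= 0.999
  for (yi in seq_along(ys)) {
    y <- ys[yi]
    d2 <- vapply(seq_len(n_tracts), function(t)
      (Xg - curve_x[yi, t])^2 + (Zg - curve_z[yi, t])^2,
      matrix(0, nx, nz))           # nx x nz x n_tracts
    slice <- matrix(bg, nx, nz)
    for (t in seq_len(n_tracts))
      slice <- slice + env[yi] * (peak[t] - bg) *
        exp(-d2[, , t] / (2 * sigma_vox^2))
    fa[, y, ] <- slice
    dmin <- apply(d2, c(1, 2), min)
    tmin <- apply(d2, c(1, 2), which.min)
    lab <- ifelse(dmin <= radius_vox^2 & env[yi] > 0.05, tmin, 0L)
    labels[, y, ] <- as.integer(lab)
  }

  ## central CSF-like ventricle (ellipsoid), away from the tract plane
  ## ventricle sits just below the tract plane, as periventricular white
  ## matter does, so ventricular expansion deforms the tracts
  vc <- c(nx / 2, ny / 2, 0.40 * nz)
  vr <- c(0.14 * nx, 0.18 * ny, 0.06 * nz)
  co <- grid_coords0(grid_shape) + 1
  e <- ((co[, 1] - vc[1]) / vr[1])^2 + ((co[, 2] - vc[2]) / vr[2])^2 +
    ((co[, 3] - vc[3]) / vr[3])^2
  ventricle <- array(e <= 1, grid_shape)
  fa[ventricle] <- 0.05
  labels[ventricle] <- 0L

  ## brain-shaped support: FA drops to zero outside an ellipsoid, as in a
  ## skull-stripped FA map; the soft edge keeps similarity metrics smooth
  bc <- c(nx, ny, nz) / 2
  br <- 0.46 * c(nx, ny, nz)
  be <- ((co[, 1] - bc[1]) / br[1])^2 + ((co[, 2] - bc[2]) / br[2])^2 +
    ((co[, 3] - bc[3]) / br[3])^2
  brain <- array(as.numeric(be <= 1), grid_shape)
  brain <- array(c_gauss3d(as.numeric(brain), grid_shape, rep(0.8, 3)),
                 grid_shape)
  fa <- fa * brain
  labels[fa < 0.15] <- 0L

  fa <- pmin(pmax(fa, 0), 1)
  ## centreline voxel = per-cross-section FA argmax within the tract label
  centrelines <- lapply(seq_len(n_tracts), function(t) {
    pts <- matrix(0L, length(ys), 3)
    keep <- logical(length(ys))
    for (yi in seq_along(ys)) {
      if (!core[yi]) next           # full-strength tube section only
      m <- labels[, ys[yi], ] == t
      if (!any(m)) next
      faslice <- fa[, ys[yi], ]
      faslice[!m] <- -1
      k <- which.max(faslice)       # first max: deterministic tie-break
      pts[yi, ] <- c((k - 1L) %% nx + 1L, ys[yi], (k - 1L) %/% nx + 1L)
      keep[yi] <- TRUE
    }
    pts[keep, , drop = FALSE]
  })

  structure(list(
    fa = fa_volume(array(fa, grid_shape), voxel_size_mm),
    labels = label_volume(labels, voxel_size_mm),
    centrelines = centrelines,
    ventricle = ventricle,
    tube_sigma_vox = sigma_vox,
    tube_radius_vox = radius_vox,
    background_fa = bg,
    seed = seed), class = "phantom_template")
}

#' @export
print.phantom_template <- function(x, ...) {
  cat(sprintf("<phantom_template> %s grid, %d tracts, seed %d\n",
              paste(dim(x$fa), collapse = "x"),
              length(x$centrelines), x$seed))
  invisible(x)
}

#' Cohort generation parameters
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed master seed; each subject derives its own stream.
#' @param warp_amplitude maximum random displacement magnitude, mm (>= 0).
#' @param warp_smoothness Gaussian smoothing width of the random field, mm.
#' @param noise_sd additive Gaussian FA noise SD (>= 0); values clamped to
#'   `[0, 1]` afterwards.
#' @param atrophy_severity dimensionless >= 0; ventricular boundary
#'   expansion as a fraction of the effective ventricle radius.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects, seed = 1, warp_amplitude = 3,
                        warp_smoothness = 8, noise_sd = 0.05,
                        atrophy_severity = 0) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (warp_amplitude < 0) stop("warp_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (atrophy_severity < 0) stop("atrophy_severity must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 warp_amplitude = warp_amplitude,
                 warp_smoothness = warp_smoothness,
                 noise_sd = noise_sd, atrophy_severity = atrophy_severity),
            class = "cohort_spec")
}

derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) + 1) * 100003 + as.numeric(k) * 7919) %%
               2147483611)
}

## smooth random displacement field: white noise per component, Gaussian
## smoothed at `smoothness_mm`, rescaled so the maximum norm equals
## `amplitude_mm`
random_smooth_field <- function(grid_shape, voxel_size, amplitude_mm,
                                smoothness_mm, seed) {
  if (amplitude_mm <= 0) return(zero_field(grid_shape, voxel_size))
  set.seed(seed)
  n <- prod(grid_shape)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  sig <- smoothness_mm / voxel_size
  for (c. in 1:3) u[, c.] <- c_gauss3d(u[, c.], grid_shape, sig)
  mx <- max(sqrt(rowSums(u^2)))
  if (mx > 0) u <- u * (amplitude_mm / mx)
  disp_field(array(u, c(grid_shape, 3L)), voxel_size)
}

#' Generate one synthetic subject from a template
#'
#' Applies a random smooth displacement field (the ground-truth warp that
#' emulates inter-individual anatomical variability), adds clamped Gaussian
#' FA noise, and returns both the image and the field.
#'
#' @param template a `phantom_template`.
#' @param spec a `cohort_spec`.
#' @param subject_index 1-based subject number; output is deterministic
#'   given `(spec$seed, subject_index)`.
#' @return list with `fa` (`fa_volume`) and `field` (`disp_field`,
#'   pull-back: resampling the template through it reproduces the noise-free
#'   subject).
#' @export
make_subject <- function(template, spec, subject_index) {
  stopifnot(inherits(template, "phantom_template"),
            inherits(spec, "cohort_spec"))
  vs <- voxel_size(template$fa)
  shape <- dim(template$fa)
  sd_seed <- derive_seed(spec$seed, subject_index)
  field <- random_smooth_field(shape, vs, spec$warp_amplitude,
                               spec$warp_smoothness, sd_seed)
  fa <- resample(template$fa, field)
  if (spec$noise_sd > 0) {
    set.seed(derive_seed(sd_seed, 1L))
    fa <- fa + array(stats::rnorm(prod(shape), 0, spec$noise_sd), shape)
  }
  fa <- fa_volume(array(pmin(pmax(fa, 0), 1), shape), vs)
  list(fa = fa, field = field)
}

#' Generate a whole cohort
#'
#' Convenience wrapper calling [make_subject()] for `1:n_subjects`.
#'
#' @inheritParams make_subject
#' @return list of `make_subject` results.
#' @export
make_cohort <- function(template, spec) {
  lapply(seq_len(spec$n_subjects), function(i)
    make_subject(template, spec, i))
}

#' Simulate atrophy-like ventricular expansion
#'
#' Deforms an FA image with a radial expansion centred on the ventricle:
#' the forward displacement points outward, growing linearly inside the
#' ventricle and decaying exponentially outside, so the low-FA ventricle
#' region dilates — the deformation regime that stresses registration in
#' neurodegeneration. The forward field is inverted numerically into the
#' pull-back field used for resampling, and optionally composed with a mild
#' random field.
#'
#' @param volume `fa_volume` to deform.
#' @param ventricle_mask logical array marking the ventricle.
#' @param severity dimensionless >= 0: the ventricle boundary moves outward
#'   by `severity` times the effective ventricle radius.
#' @param seed seed for the random component (ignored if
#'   `random_amplitude_mm = 0`).
#' @param random_amplitude_mm amplitude of the additional random field (mm).
#' @param random_smoothness_mm smoothness of the random component (mm).
#' @return list with `fa` (deformed image), `field` (pull-back
#'   `disp_field` reproducing `fa` by resampling), and `forward_field` (the
#'   analytic expansion field; positive divergence inside the ventricle).
#' @export
simulate_atrophy <- function(volume, ventricle_mask, severity, seed = 1,
                             random_amplitude_mm = 0,
                             random_smoothness_mm = 8) {
  if (severity < 0) stop("severity must be >= 0")
  if (!any(ventricle_mask)) stop("ventricle mask is empty")
  shape <- dim(volume)[1:3]
  vs <- voxel_size(volume)
  idx <- which(ventricle_mask)
  co <- grid_coords0(shape)
  ctr_vox <- colMeans(co[idx, , drop = FALSE])
  ctr_mm <- ctr_vox * vs
  vol_mm3 <- length(idx) * prod(vs)
  r0 <- (3 * vol_mm3 / (4 * pi))^(1 / 3)   # effective ventricle radius, mm

  w <- sweep(co, 2, vs, "*")
  dv <- sweep(w, 2, ctr_mm, "-")
  r <- sqrt(rowSums(dv^2))
  rho <- ifelse(r < r0, r / r0, exp(-(r - r0) / r0))
  mag <- severity * r0 * rho
  rhat <- dv / pmax(r, 1e-9)
  uf <- rhat * mag
  forward <- disp_field(array(uf, c(shape, 3L)), vs)

  if (severity > 0) {
    field <- invert_field(forward)
  } else {
    field <- zero_field(shape, vs)
  }
  if (random_amplitude_mm > 0) {
    rf <- random_smooth_field(shape, vs, random_amplitude_mm,
                              random_smoothness_mm, derive_seed(seed, 97L))
    field <- compose_transforms(rf, field)
  }
  fa <- resample(volume, field)
  list(fa = fa, field = field, forward_field = forward)
}

#' Reduce FA inside a mask by a fixed fraction
#'
#' Multiplies FA by `(1 - fraction)` inside the mask and leaves all other
#' voxels untouched — the planted group difference of the sensitivity
#' experiment.
#'
#' @param volume `fa_volume`.
#' @param mask logical array (or 0/1 volume) on the same grid.
#' @param fraction reduction fraction in `[0, 1)`.
#' @export
reduce_fa <- function(volume, mask, fraction) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1), got ", fraction)
  mask <- array(as.logical(as.numeric(mask) != 0), dim(volume)[1:3])
  out <- as_num3(volume)
  out[mask] <- out[mask] * (1 - fraction)
  fa_volume(out, voxel_size(volume))
}
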