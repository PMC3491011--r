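#' Voxel-wise mean FA of an aligned cohort
#'
#' @param cohort an `aligned_cohort` or a list of `fa_volume`s on one grid.
#' @return An `fa_volume`.
#' @export
mean_fa <- function(cohort) {
  vols <- as_volume_list(cohort)
  if (length(vols) < 2) stop("mean FA needs at least 2 aligned subjects")
  shape <- grid_shape(vols[[1]]); vs <- voxel_size(vols[[1]])
  for (v in vols)
    if (!identical(grid_shape(v), shape))
      stop("aligned volumes are not on a common grid")
  acc <- array(0, shape)
  for (v in vols) acc <- acc + as_num3(v)
  fa_volume(acc / length(vols), vs)
}

## accept aligned_cohort, list of volumes, or list of make_subject results
as_volume_list <- function(x) {
  if (inherits(x, "aligned_cohort")) return(x$aligned)
  if (inherits(x, "fa_volume")) return(list(x))
  stopifnot(is.list(x))
  lapply(x, function(el) {
    if (inherits(el, "fa_volume")) el
    else if (is.list(el) && inherits(el$fa, "fa_volume")) el$fa
    else stop("expected fa_volume elements")
  })
}

#' White-matter skeletonisation of a mean FA map
#'
#' Identifies centre-of-tract voxels: a voxel joins the skeleton when its
#' mean FA exceeds `fa_threshold` and it is a local maximum of FA along the
#' tract-perpendicular direction, estimated as the eigenvector of the most
#' negative eigenvalue of the local FA Hessian (computed on a
#' Gaussian-smoothed copy, sigma = 1 voxel). The per-voxel search direction
#' is stored for the projection step.
#'
#' @param mean_fa_volume `fa_volume` of mean FA (values in `[0, 1]`).
#' @param fa_threshold FA threshold; the conventional 0.2 by default, set to
#'   include major pathways while excluding peripheral tracts.
#' @param smooth_sigma_vox smoothing (voxels) for direction estimation.
#' @param min_component minimum connected-component size kept (26-
#'   connectivity); prunes isolated spurious maxima.
#' @return An object of class `skeleton`: `mask` (logical array), `idx`
#'   (linear indices), `coords` (V x 3, 1-based), `directions` (V x 3 unit
#'   vectors, mm space), `fa_threshold`, `voxel_size`.
#' @export
skeletonize <- function(mean_fa_volume, fa_threshold = 0.2,
                        smooth_sigma_vox = 1, min_component = 5) {
  shape <- grid_shape(mean_fa_volume)
  vs <- voxel_size(mean_fa_volume)
  fa <- as_num3(mean_fa_volume)
  cand <- which(fa > fa_threshold)
  if (length(cand) == 0) {
    warning("no voxels above the FA threshold; returning an empty skeleton")
    return(structure(list(mask = array(FALSE, shape),
                          idx = integer(0),
                          coords = matrix(0L, 0, 3),
                          directions = matrix(0, 0, 3),
                          directions2 = matrix(0, 0, 3),
                          tangents = matrix(0, 0, 3),
                          fa_threshold = fa_threshold, voxel_size = vs),
                     class = "skeleton"))
  }
  sm <- c_gauss3d(as.numeric(fa), shape, rep(smooth_sigma_vox, 3))
  ## Hessian rows = gradients of the gradient components (per mm^2)
  g <- c_gradient(sm, shape, vs)
  Hcols <- lapply(1:3, function(c.) c_gradient(g[, c.], shape, vs))
  dirs <- matrix(0, length(cand), 3)
  dirs2 <- matrix(0, length(cand), 3)
  tangents <- matrix(0, length(cand), 3)
  for (i in seq_along(cand)) {
    k <- cand[i]
    H <- cbind(Hcols[[1]][k, ], Hcols[[2]][k, ], Hcols[[3]][k, ])
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    dirs[i, ] <- ev$vectors[, 3]     # most negative curvature direction
    dirs2[i, ] <- ev$vectors[, 2]    # second perpendicular direction
    tangents[i, ] <- ev$vectors[, 1] # tract tangent (least curvature)
  }
  ## centre-of-gravity local-maximum test (the classic TBSS rule): the
  ## offset of the FA-weighted centre of gravity of the 3x3x3 neighbourhood
  ## estimates where the tract mass lies. Off-centre voxels (offset >= 0.1
  ## voxel) must beat the FA one integer step along +/- that direction;
  ## plateau-centre voxels are tested along the integer axis with the
  ## steepest fall-off. Integer offsets keep comparisons exact and the
  ## skeleton a single voxel thick.
  co0 <- grid_coords0(shape)[cand, , drop = FALSE]
  s0 <- fa[cand]
  samp <- function(off) {
    p <- sweep(co0, 2, off, "+")
    inb <- p[, 1] >= 0 & p[, 2] >= 0 & p[, 3] >= 0 &
      p[, 1] < shape[1] & p[, 2] < shape[2] & p[, 3] < shape[3]
    out <- numeric(nrow(p))
    k <- p[inb, 1] + shape[1] * (p[inb, 2] + shape[2] * p[inb, 3]) + 1
    out[inb] <- fa[k]
    out
  }
  offs27 <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  wsum <- numeric(length(cand))
  cog <- matrix(0, length(cand), 3)
  for (o in seq_len(nrow(offs27))) {
    w <- samp(offs27[o, ])
    wsum <- wsum + w
    cog <- cog + outer(w, offs27[o, ])
  }
  cog <- cog / pmax(wsum, 1e-12)
  cogn <- sqrt(rowSums(cog^2))
  ## 13 unique integer axes of the 26-neighbourhood
  axes13 <- offs27[seq_len(13), , drop = FALSE]
  off_centre <- cogn >= 0.1
  keep <- logical(length(cand))
  ## off-centre: integer direction nearest the CoG offset
  dirn <- round(cog / pmax(cogn, 1e-12))
  for (o in seq_len(nrow(axes13))) {
    ax <- axes13[o, ]
    selp <- off_centre & ((dirn[, 1] == ax[1] & dirn[, 2] == ax[2] &
                             dirn[, 3] == ax[3]) |
                            (dirn[, 1] == -ax[1] & dirn[, 2] == -ax[2] &
                               dirn[, 3] == -ax[3]))
    if (!any(selp)) next
    fp <- samp(ax); fm <- samp(-ax)
    keep[selp] <- s0[selp] >= fp[selp] & s0[selp] > fm[selp]
  }
  ## plateau centres: steepest fall-off axis
  ctr <- which(!off_centre)
  if (length(ctr)) {
    best_sum <- rep(Inf, length(ctr)); second_sum <- rep(Inf, length(ctr))
    best_ok <- logical(length(ctr)); second_ok <- logical(length(ctr))
    for (o in seq_len(nrow(axes13))) {
      ax <- axes13[o, ]
      fp <- samp(ax)[ctr]; fm <- samp(-ax)[ctr]
      sums <- fp + fm
      oks <- s0[ctr] >= fp & s0[ctr] > fm        # strict one side
      okw <- s0[ctr] >= fp & s0[ctr] >= fm       # weak (flat ridges pass)
      b <- sums < best_sum
      second_sum[b] <- best_sum[b]; second_ok[b] <- best_ok[b]
      best_sum[b] <- sums[b]; best_ok[b] <- oks[b]
      s2 <- !b & sums < second_sum
      second_sum[s2] <- sums[s2]; second_ok[s2] <- okw[s2]
    }
    keep[ctr] <- best_ok & second_ok
  }
  ## cross-section uniqueness: drop a voxel when an adjacent kept voxel in
  ## (approximately) the same cross-section carries higher FA — along-tract
  ## neighbours (large tangential offset) are never suppressed
  surv <- which(keep)
  if (length(surv) > 1) {
    sc <- co0[surv, , drop = FALSE]
    sfa <- s0[surv]
    drop <- logical(length(surv))
    for (a in seq_along(surv)) {
      dv <- sweep(sc, 2, sc[a, ], "-")
      dist2 <- rowSums(dv^2)
      near <- which(dist2 > 0 & dist2 <= 2.1 & sfa > sfa[a])
      if (length(near) == 0) next
      ax <- abs(dv[near, , drop = FALSE] %*% tangents[surv[a], ])
      if (any(ax < 0.5)) drop[a] <- TRUE
    }
    keep[surv[drop]] <- FALSE
  }
  ## prune isolated fragments: genuine tract skeletons are extended chains
  surv <- which(keep)
  if (length(surv) > 1 && min_component > 1) {
    adj <- skeleton_adjacency(co0[surv, , drop = FALSE] + 1L)
    comp <- rep(NA_integer_, length(surv))
    for (v in seq_along(surv)) {
      if (!is.na(comp[v])) next
      q <- v; comp[v] <- v
      while (length(q)) {
        u <- q[1]; q <- q[-1]
        nb <- adj$adj[seq.int(adj$start[u] + 1L,
                              length.out = adj$start[u + 1L] -
                                adj$start[u])] + 1L
        new <- nb[is.na(comp[nb])]
        comp[new] <- v
        q <- c(q, new)
      }
    }
    sizes <- table(comp)
    small <- as.integer(names(sizes)[sizes < min_component])
    keep[surv[comp %in% small]] <- FALSE
  }
  idx <- cand[keep]
  mask <- array(FALSE, shape); mask[idx] <- TRUE
  structure(list(mask = mask, idx = idx,
                 coords = grid_coords0(shape)[idx, , drop = FALSE] + 1L,
                 directions = dirs[keep, , drop = FALSE],
                 directions2 = dirs2[keep, , drop = FALSE],
                 tangents = tangents[keep, , drop = FALSE],
                 fa_threshold = fa_threshold, voxel_size = vs),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d voxels, FA threshold %.2f\n",
              length(x$idx), x$fa_threshold))
  invisible(x)
}

## nearest-skeleton-voxel partition (owner id + distance in mm) of the
## search neighbourhood, bounding each skeleton voxel's search region
skeleton_owner_map <- function(skeleton, shape, reach_mm) {
  c_owner_partition(shape, skeleton$voxel_size,
                    as.integer(skeleton$idx - 1L), reach_mm)
}

#' Project one subject's FA onto the skeleton
#'
#' For each skeleton voxel, searches its tract-perpendicular neighbourhood
#' — grid voxels within `max_search_mm` whose offset lies in the
#' cross-sectional slab (axial component below ~half a voxel) — and records
#' the maximum FA found, the subject's local tract-centre value. The search
#' is bounded by the nearest-skeleton-voxel partition: a voxel may only be
#' claimed while the searching skeleton voxel is, to within one voxel, its
#' nearest skeleton voxel, which keeps correspondences local and stops two
#' distant skeleton voxels from competing for the same maximum. Sampling at
#' integer voxel offsets returns exact voxel values (no interpolation loss
#' at tract peaks).
#'
#' @param subject_fa `fa_volume` on the skeleton grid.
#' @param skeleton a `skeleton`.
#' @param max_search_mm search limit in mm (default 8); 0 means the skeleton
#'   voxel's own value.
#' @param owner optional precomputed owner map (internal reuse).
#' @return Numeric vector, one projected FA value per skeleton voxel.
#' @export
project <- function(subject_fa, skeleton, max_search_mm = 8, owner = NULL) {
  shape <- grid_shape(subject_fa)
  vs <- skeleton$voxel_size
  nv <- length(skeleton$idx)
  if (nv == 0) return(numeric(0))
  fa <- as.numeric(subject_fa)
  if (max_search_mm <= 0) return(fa[skeleton$idx])
  if (is.null(owner)) owner <- skeleton_owner_map(skeleton, shape, max_search_mm)
  slack_mm <- mean(vs)
  best <- fa[skeleton$idx]
  ownerv <- owner$owner
  distv <- owner$dist_mm
  co0 <- skeleton$coords - 1L
  rad <- floor(max_search_mm / vs)
  offs <- as.matrix(expand.grid(x = -rad[1]:rad[1], y = -rad[2]:rad[2],
                                z = -rad[3]:rad[3]))
  off_mm2 <- (offs^2) %*% (vs^2)
  offs <- offs[off_mm2 > 0 & off_mm2 <= max_search_mm^2, , drop = FALSE]
  self <- seq_len(nv)
  for (o in seq_len(nrow(offs))) {
    off <- offs[o, ]
    t_mm <- sqrt(sum((off * vs)^2))
    ## perpendicularity: axial (tangent) component of the offset < ~half
    ## a voxel, so the scan covers the cross-sectional slab
    axial <- abs(as.numeric(skeleton$tangents %*% (off * vs))) / mean(vs)
    p <- sweep(co0, 2, off, "+")
    inb <- p[, 1] >= 0 & p[, 2] >= 0 & p[, 3] >= 0 &
      p[, 1] < shape[1] & p[, 2] < shape[2] & p[, 3] < shape[3]
    sel <- which(inb & axial <= 0.6)
    if (length(sel) == 0) next
    k <- p[sel, 1] + shape[1] * (p[sel, 2] + shape[2] * p[sel, 3]) + 1
    own <- ownerv[k]; dst <- distv[k]
    ok <- own > 0 & dst >= 0 & (own == self[sel] | t_mm <= dst + slack_mm)
    ksel <- sel[ok]
    best[ksel] <- pmax(best[ksel], fa[k[ok]])
  }
  best
}

#' Project a whole cohort onto the skeleton
#'
#' @param cohort `aligned_cohort` or list of volumes on the skeleton grid.
#' @inheritParams project
#' @param subject_ids optional subject labels.
#' @return A `projected_matrix`: subjects x skeleton-voxels matrix with the
#'   voxel coordinates as attribute `coords` and the skeleton as attribute
#'   `skeleton`.
#' @export
project_cohort <- function(cohort, skeleton, max_search_mm = 8,
                           subject_ids = NULL) {
  vols <- as_volume_list(cohort)
  shape <- grid_shape(vols[[1]])
  owner <- if (max_search_mm > 0)
    skeleton_owner_map(skeleton, shape, max_search_mm) else NULL
  rows <- lapply(vols, project, skeleton = skeleton,
                 max_search_mm = max_search_mm, owner = owner)
  m <- do.call(rbind, rows)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_along(vols))
  rownames(m) <- subject_ids
  structure(m, coords = skeleton$coords, skeleton = skeleton,
            class = c("projected_matrix", "matrix"))
}

#' Voxel-wise standard deviation map of an aligned cohort
#'
#' Sample standard deviation (n - 1 denominator) of FA across subjects at
#' every voxel; the alignment-quality diagnostic.
#'
#' @param cohort `aligned_cohort` or list of volumes on one grid.
#' @return An `fa_volume`-classed array of per-voxel SD.
#' @export
groupwise_sd_map <- function(cohort) {
  vols <- as_volume_list(cohort)
  if (length(vols) < 2) stop("SD map needs at least 2 subjects")
  shape <- grid_shape(vols[[1]]); vs <- voxel_size(vols[[1]])
  n <- length(vols)
  s1 <- array(0, shape); s2 <- array(0, shape)
  for (v in vols) { a <- as_num3(v); s1 <- s1 + a; s2 <- s2 + a * a }
  va <- pmax((s2 - s1^2 / n) / (n - 1), 0)
  fa_volume(sqrt(va), vs)
}
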