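## Common-space alignment strategies. All four return an `aligned_cohort`
## on the standard-template grid, so downstream skeleton/stats code is
## strategy-agnostic.

new_aligned_cohort <- function(aligned, transforms, strategy, reference,
                               trace = NULL, representative = NA_integer_) {
  structure(list(aligned = aligned, transforms = transforms,
                 strategy = strategy, reference = reference,
                 trace = trace, representative = representative),
            class = "aligned_cohort")
}

#' @export
print.aligned_cohort <- function(x, ...) {
  cat(sprintf("<aligned_cohort> %s, %d subjects on %s grid\n", x$strategy,
              length(x$aligned), paste(grid_shape(x$reference),
                                       collapse = "x")))
  invisible(x)
}

#' Mean cohort variance of difference
#'
#' Mean over voxels of the per-voxel variance (across subjects) of the
#' aligned images about their average — the alignment-quality scalar traced
#' across group-wise atlas iterations.
#'
#' @param cohort an `aligned_cohort` or list of volumes.
#' @export
cohort_variance <- function(cohort) {
  vols <- as_volume_list(cohort)
  n <- length(vols)
  shape <- grid_shape(vols[[1]])
  s1 <- array(0, shape); s2 <- array(0, shape)
  for (v in vols) { a <- as_num3(v); s1 <- s1 + a; s2 <- s2 + a * a }
  mean(pmax((s2 - s1^2 / n) / (n - 1), 0))
}

## linear + non-rigid (pipeline algorithm) registration of one subject to a
## target; returns the composite pull-back field on the target grid
register_to_target <- function(subject, target, linear_kind = "affine") {
  A <- register_linear(subject, target, linear_kind)
  lin <- resample(subject, A, reference = target)
  F <- register_nonrigid(lin, target, "pipeline")
  compose_transforms(F, A)      # apply A, then F
}

#' Pass-through alignment for pre-aligned cohorts
#'
#' Wraps subjects that are already on a common grid as an `aligned_cohort`
#' with identity transforms — used for null-calibration experiments where
#' the groups share the same anatomy by construction and registration would
#' be a no-op.
#'
#' @param subjects list of `fa_volume`s on one grid.
#' @param reference optional reference volume (defaults to the first
#'   subject).
#' @export
align_identity <- function(subjects, reference = NULL) {
  vols <- as_volume_list(subjects)
  if (length(vols) < 2) stop("need at least 2 subjects")
  ref <- if (is.null(reference)) vols[[1]] else reference
  shape <- grid_shape(ref); vs <- voxel_size(ref)
  tr <- lapply(vols, function(v) zero_field(shape, vs))
  new_aligned_cohort(vols, tr, "PRE", ref)
}

#' Standard-template alignment (ST)
#'
#' Every subject is registered directly — linearly, then non-rigidly — to
#' the standard-space template, and resampled trilinearly onto its grid.
#'
#' @param subjects list of native `fa_volume`s (or `make_subject` results).
#' @param template `fa_volume`, the standard-space target.
#' @return An `aligned_cohort` with strategy `"ST"`.
#' @export
align_standard <- function(subjects, template) {
  vols <- as_volume_list(subjects)
  if (length(vols) < 2) stop("need at least 2 subjects")
  transforms <- vector("list", length(vols))
  aligned <- vector("list", length(vols))
  for (i in seq_along(vols)) {
    tr <- tryCatch(register_to_target(vols[[i]], template),
                   error = function(e)
                     stop("registration failed for subject ", i, ": ",
                          conditionMessage(e)))
    transforms[[i]] <- tr
    aligned[[i]] <- resample(vols[[i]], tr, reference = template)
  }
  new_aligned_cohort(aligned, transforms, "ST", template)
}

#' Most-representative-subject alignment (RS)
#'
#' Performs pairwise registrations between subjects and selects as the
#' reference the subject needing the minimum mean non-rigid deformation to
#' align it to all the others. That reference is then affine-aligned to the
#' standard template and every subject reaches template space by composing
#' its non-rigid transform to the reference with that affine.
#'
#' @inheritParams align_standard
#' @param pair_level integer downsampling factor for the pairwise
#'   selection registrations (the composite transforms to template space
#'   are recomputed at full resolution); 1 = full resolution.
#' @param max_pairs optional cap on the number of ordered pairs registered
#'   (taken in fixed row-major order; magnitudes for missing pairs are
#'   excluded from the means).
#' @return An `aligned_cohort` with strategy `"RS"`; element
#'   `representative` holds the selected index, attribute
#'   `mean_deformation` the per-candidate table.
#' @export
select_representative <- function(subjects, template = NULL, pair_level = 2,
                                  max_pairs = Inf) {
  vols <- as_volume_list(subjects)
  n <- length(vols)
  if (n < 3) stop("representative selection needs at least 3 subjects")
  small <- if (pair_level > 1) lapply(vols, downsample_volume, pair_level)
           else vols
  D <- matrix(NA_real_, n, n)   # D[i, j] = |field| aligning i (moving) to j
  pairs <- which(upper.tri(matrix(0, n, n)) | lower.tri(matrix(0, n, n)),
                 arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  if (is.finite(max_pairs) && nrow(pairs) > max_pairs)
    pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    A <- register_linear(small[[i]], small[[j]], "affine")
    lin <- resample(small[[i]], A, reference = small[[j]])
    F <- register_nonrigid(lin, small[[j]], "pipeline")
    D[i, j] <- deformation_magnitude(F)
  }
  ## mean non-rigid deformation needed to bring every other subject onto
  ## candidate s (the same direction as the transforms reused below)
  mean_def <- vapply(seq_len(n), function(s)
    mean(D[-s, s], na.rm = TRUE), numeric(1))
  r <- which.min(mean_def)      # which.min takes the lowest index on ties
  if (sum(abs(mean_def - mean_def[r]) < 1e-12) > 1)
    message("tie in mean deformation; selecting lowest index ", r)

  ref <- vols[[r]]
  transforms <- vector("list", n)
  aligned <- vector("list", n)
  if (!is.null(template)) {
    A_ref <- register_linear(ref, template, "affine")
    out_ref <- template
  } else {
    A_ref <- NULL
    out_ref <- ref
  }
  for (i in seq_len(n)) {
    if (i == r) {
      tr <- if (is.null(A_ref)) zero_field(grid_shape(ref), voxel_size(ref))
            else compose_transforms(A_ref, zero_field(grid_shape(ref),
                                                      voxel_size(ref)),
                                    reference = template)
    } else {
      to_ref <- register_to_target(vols[[i]], ref)
      tr <- if (is.null(A_ref)) to_ref
            else compose_transforms(A_ref, to_ref, reference = template)
    }
    transforms[[i]] <- tr
    aligned[[i]] <- resample(vols[[i]], tr, reference = out_ref)
  }
  ref_img <- if (is.null(A_ref)) ref
             else resample(ref, A_ref, reference = template)
  out <- new_aligned_cohort(aligned, transforms, "RS", ref_img,
                            representative = r)
  attr(out, "mean_deformation") <- mean_def
  out
}

#' Study-specific-template alignment (SS)
#'
#' Stage 1 aligns all subjects to the standard template; stage 2 averages
#' them into a study-specific template; stage 3 re-registers each original
#' native image (linearly + non-rigidly) to that average, which becomes the
#' reference image of the returned cohort.
#'
#' @inheritParams align_standard
#' @return An `aligned_cohort` with strategy `"SS"`; the reference image is
#'   the stage-2 mean.
#' @export
build_study_template <- function(subjects, template) {
  vols <- as_volume_list(subjects)
  stage1 <- align_standard(vols, template)
  study_template <- mean_fa(stage1)
  transforms <- vector("list", length(vols))
  aligned <- vector("list", length(vols))
  for (i in seq_along(vols)) {
    tr <- register_to_target(vols[[i]], study_template)
    transforms[[i]] <- tr
    aligned[[i]] <- resample(vols[[i]], tr, reference = study_template)
  }
  out <- new_aligned_cohort(aligned, transforms, "SS", study_template)
  attr(out, "stage1") <- stage1
  out
}

#' Iterative group-wise atlas alignment (GW)
#'
#' Two-step iterative atlas construction: register every input to the
#' current atlas with the iteration's deformation model, then update the
#' atlas as the voxel-wise mean of the registered images. The schedule is
#' coarse-to-fine — the first iteration is rigid-only so the random choice
#' of the initial atlas subject introduces no bias, followed by affine and
#' then non-rigid iterations. The per-iteration mean variance of the
#' difference between atlas and registered subjects is recorded. The
#' converged atlas is affine-registered to the standard template and that
#' affine is composed into every subject's transform.
#'
#' @inheritParams align_standard
#' @param schedule character vector of stage tags (`"rigid"`, `"affine"`,
#'   `"nonrigid"`); must start with `"rigid"`. Default: 1 rigid, 4 affine,
#'   10 non-rigid iterations.
#' @param seed seed selecting the initial atlas subject (required).
#' @param early_stop_frac stop early when the variance improves by less
#'   than this fraction between consecutive same-stage iterations (0
#'   disables).
#' @param keep_atlases keep the per-iteration atlas volumes in the trace.
#' @return An `aligned_cohort` with strategy `"GW"` and element `trace`
#'   (list with `variance`, `schedule`, optionally `atlases`).
#' @export
build_groupwise_atlas <- function(subjects, template = NULL,
                                  schedule = c("rigid", rep("affine", 4),
                                               rep("nonrigid", 10)),
                                  seed = 1, early_stop_frac = 0.001,
                                  keep_atlases = FALSE) {
  vols <- as_volume_list(subjects)
  n <- length(vols)
  if (n < 2) stop("need at least 2 subjects")
  schedule <- match.arg(schedule, c("rigid", "affine", "nonrigid"),
                        several.ok = TRUE)
  if (schedule[1] != "rigid")
    stop("schedule must start with a rigid iteration (unbiased start)")
  if (is.null(seed)) stop("a seed is required to pick the initial atlas")
  set.seed(seed)
  init <- sample.int(n, 1)
  atlas <- vols[[init]]
  variance <- numeric(0)
  stages_run <- character(0)
  atlases <- list()
  transforms <- vector("list", n)
  aligned <- vector("list", n)
  affine_cache <- vector("list", n)   # subject -> atlas affine, reused
                                      # across non-rigid iterations
  for (it in seq_along(schedule)) {
    stage <- schedule[it]
    prev_aligned <- aligned; prev_transforms <- transforms
    for (i in seq_len(n)) {
      if (stage == "rigid") {
        A <- register_linear(vols[[i]], atlas, "rigid")
        transforms[[i]] <- A
      } else if (stage == "affine") {
        A <- register_linear(vols[[i]], atlas, "affine")
        transforms[[i]] <- A
        affine_cache[[i]] <- A
      } else {
        A <- affine_cache[[i]]
        if (is.null(A)) {
          A <- register_linear(vols[[i]], atlas, "affine")
          affine_cache[[i]] <- A
        }
        lin <- resample(vols[[i]], A, reference = atlas)
        F <- register_nonrigid(lin, atlas, "pipeline")
        transforms[[i]] <- compose_transforms(F, A)
      }
      aligned[[i]] <- resample(vols[[i]], transforms[[i]], reference = atlas)
    }
    new_atlas <- mean_fa(aligned)
    newvar <- cohort_variance(aligned)
    k <- length(variance)
    converged <- early_stop_frac > 0 && stage == "nonrigid" && k >= 1 &&
      stages_run[k] == "nonrigid" &&
      (variance[k] - newvar) < early_stop_frac * variance[k]
    if (converged && newvar > variance[k]) {
      ## the update did not improve the atlas: discard it and stop
      aligned <- prev_aligned; transforms <- prev_transforms
      break
    }
    variance <- c(variance, newvar)
    stages_run <- c(stages_run, stage)
    if (keep_atlases) atlases[[length(atlases) + 1]] <- new_atlas
    atlas <- new_atlas
    if (converged) break
  }
  trace <- list(variance = variance, schedule = stages_run,
                atlases = if (keep_atlases) atlases else NULL,
                init_subject = init)
  if (!is.null(template)) {
    A_t <- register_linear(atlas, template, "affine")
    for (i in seq_len(n)) {
      transforms[[i]] <- compose_transforms(A_t, transforms[[i]],
                                            reference = template)
      aligned[[i]] <- resample(vols[[i]], transforms[[i]],
                               reference = template)
    }
    atlas <- resample(atlas, A_t, reference = template)
  }
  new_aligned_cohort(aligned, transforms, "GW", atlas, trace = trace,
                     representative = init)
}

#' Build a common-space cohort with a named strategy
#'
#' Dispatcher over the four reference strategies.
#'
#' @inheritParams align_standard
#' @param strategy one of `"st"`, `"rs"`, `"ss"`, `"gw"`, or `"none"`
#'   (pre-aligned pass-through).
#' @param seed seed for strategies that need one (GW atlas initialisation).
#' @param ... passed to the strategy function.
#' @export
build_reference <- function(subjects, template,
                            strategy = c("st", "rs", "ss", "gw", "none"),
                            seed = 1, ...) {
  strategy <- match.arg(tolower(strategy), c("st", "rs", "ss", "gw", "none"))
  switch(strategy,
         st = align_standard(subjects, template),
         rs = select_representative(subjects, template, ...),
         ss = build_study_template(subjects, template),
         gw = build_groupwise_atlas(subjects, template, seed = seed, ...),
         none = align_identity(subjects, template))
}
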