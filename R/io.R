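#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 image (gzip transparent) into an `fa_volume` or
#' `label_volume`, carrying over the voxel size from the header.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param type `"fa"` (default) or `"label"`.
#' @export
read_volume <- function(path, type = c("fa", "label")) {
  type <- match.arg(type)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("'", path, "' is ", length(d), "D; expected a 3D volume")
  vs <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), d)
  if (type == "label") label_volume(arr, vs) else fa_volume(arr, vs)
}

#' Write a volume as NIfTI-1
#'
#' @param volume `fa_volume` or `label_volume`.
#' @param path output path; `.nii.gz` compresses.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(array(as.numeric(volume), grid_shape(volume)))
  RNifti::pixdim(img) <- voxel_size(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write displacement fields as 4D NIfTI
#'
#' Fields are stored as 4D images (last axis = vector component, mm units,
#' pull-back convention).
#'
#' @param path file path.
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("'", path, "' is not a 4D displacement field with 3 components")
  disp_field(array(as.numeric(img), d), RNifti::pixdim(img)[1:3])
}

#' @rdname read_field
#' @param field a `disp_field`.
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(array(as.numeric(field), dim(field)))
  RNifti::pixdim(img) <- c(voxel_size(field), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an affine transform as a plain-text 4x4 matrix
#' @param transform an `affine_transform`.
#' @param path output path.
#' @export
write_affine <- function(transform, path) {
  utils::write.table(transform$matrix, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @param kind transform kind for validation on read.
#' @export
read_affine <- function(path, kind = "affine") {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  affine_transform(m, kind)
}

#' Write a projected matrix with its voxel-coordinate sidecar
#'
#' The matrix is written as TSV (rows = subjects, columns = skeleton voxel
#' linear column ids) and a JSON sidecar maps columns to 1-based voxel
#' coordinates.
#'
#' @param matrix a `projected_matrix`.
#' @param path TSV output path; the sidecar gets `.json` appended.
#' @export
write_projected_matrix <- function(matrix, path) {
  m <- unclass(matrix)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  co <- attr(matrix, "coords")
  jsonlite::write_json(
    list(columns = lapply(seq_len(nrow(co)), function(i) co[i, ])),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the tunable parameters of an end-to-end run with their
#' conventional defaults: skeleton threshold 0.2, 5000 permutations,
#' corrected alpha 0.05.
#'
#' @param strategy reference strategy.
#' @param fa_threshold skeleton FA threshold.
#' @param max_search_mm projection search limit.
#' @param n_permutations permutation count.
#' @param alpha corrected significance level.
#' @param seed master seed.
#' @param tfce_E,tfce_H TFCE exponents.
#' @param out_dir optional output directory for artifacts.
#' @export
run_config <- function(strategy = "gw", fa_threshold = 0.2,
                       max_search_mm = 8, n_permutations = 5000,
                       alpha = 0.05, seed = 1, tfce_E = 0.5, tfce_H = 2,
                       out_dir = NULL) {
  stopifnot(fa_threshold >= 0, fa_threshold < 1, alpha > 0, alpha < 1,
            n_permutations >= 1)
  structure(list(strategy = strategy, fa_threshold = fa_threshold,
                 max_search_mm = max_search_mm,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = as.integer(seed),
                 tfce_E = tfce_E, tfce_H = tfce_H, out_dir = out_dir),
            class = "run_config")
}

#' Run the end-to-end TBSS pipeline
#'
#' Composes reference construction, mean FA, skeletonisation, projection
#' and permutation statistics; optionally writes all intermediates (mean
#' FA, skeleton mask, projected matrix, stat tables and a provenance
#' manifest) under `config$out_dir`. Idempotent for fixed seeds.
#'
#' @param config a `run_config`.
#' @param subjects list of native `fa_volume`s.
#' @param template standard-space `fa_volume`.
#' @param group group label per subject (two levels).
#' @param covariates optional nuisance covariates.
#' @return list with `cohort`, `mean_fa`, `skeleton`, `matrix`, `stats` and
#'   `report` (a small summary data.frame).
#' @export
run_pipeline <- function(config, subjects, template, group,
                         covariates = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    message(sprintf("[gwtbss] %-12s ...", name))
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    message(sprintf("[gwtbss] %-12s done (%.1f s)", name,
                    proc.time()[3] - t0))
    out
  }
  cohort <- stage("reference", build_reference(subjects, template,
                                               config$strategy,
                                               seed = config$seed))
  mfa <- stage("mean_fa", mean_fa(cohort))
  skel <- stage("skeleton", skeletonize(mfa, config$fa_threshold))
  if (length(skel$idx) == 0) stop("pipeline stage 'skeleton' failed: empty")
  pm <- stage("project", project_cohort(cohort, skel, config$max_search_mm))
  des <- design_info(group, covariates)
  st <- stage("stats", permutation_fwe(pm, des,
                                       n_permutations = config$n_permutations,
                                       seed = config$seed,
                                       alpha = config$alpha,
                                       E = config$tfce_E, H = config$tfce_H))
  p_any <- pmin(st$p_fwe_increase, st$p_fwe_decrease)
  report <- data.frame(strategy = toupper(config$strategy),
                       n_subjects = length(as_volume_list(subjects)),
                       n_skeleton_voxels = length(skel$idx),
                       n_significant_voxels = sum(p_any < config$alpha),
                       min_p_fwe = min(p_any),
                       n_permutations = st$n_permutations,
                       alpha = config$alpha, seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_volume(mfa, file.path(od, "mean_fa.nii.gz"))
    write_volume(fa_volume(array(as.numeric(skel$mask), dim(skel$mask)),
                           skel$voxel_size),
                 file.path(od, "skeleton_mask.nii.gz"))
    write_projected_matrix(pm, file.path(od, "projected_fa.tsv"))
    utils::write.table(
      data.frame(voxel = seq_along(st$tstat), t = st$tstat,
                 tfce_increase = st$tfce_increase,
                 tfce_decrease = st$tfce_decrease,
                 p_fwe_increase = st$p_fwe_increase,
                 p_fwe_decrease = st$p_fwe_decrease),
      file.path(od, "voxelwise_stats.tsv"), sep = "\t", row.names = FALSE)
    utils::write.csv(report, file.path(od, "report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(package = "gwtbss",
           version = as.character(utils::packageVersion("gwtbss")),
           config = unclass(config), timestamp = format(Sys.time())),
      file.path(od, "manifest.json"), auto_unbox = TRUE, null = "null")
  }
  list(cohort = cohort, mean_fa = mfa, skeleton = skel, matrix = pm,
       stats = st, report = report)
}
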