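test_that("affine transforms validate their invariants", {
  expect_error(affine_transform(matrix(0, 4, 4)), "invertible")
  M <- diag(4); M[1, 1] <- 2
  expect_error(affine_transform(M, "rigid"), "orthonormal")
  expect_s3_class(affine_transform(M, "affine"), "affine_transform")
  tr <- affine_transform(diag(4), "rigid")
  expect_equal(affine_inverse(tr)$matrix, diag(4))
})

test_that("resampling preserves identity, shifts and label sets", {
  tp <- fix_small_template()
  out <- resample(tp$fa, affine_transform(diag(4)))
  expect_identical(as.numeric(out), as.numeric(tp$fa))
  out0 <- resample(tp$fa, zero_field(dim(tp$fa), voxel_size(tp$fa)))
  expect_identical(as.numeric(out0), as.numeric(tp$fa))

  ## integer-voxel translation with nearest: a shifted copy, no new values
  M <- diag(4); M[1, 4] <- voxel_size(tp$fa)[1]
  sh <- resample(tp$fa, affine_transform(M), "nearest")
  expect_identical(sh[1:30, , ], unclass(tp$fa)[2:31, , ],
                   ignore_attr = TRUE)
  lab <- resample(tp$labels, affine_transform(M), "nearest")
  expect_true(all(unique(as.integer(lab)) %in% unique(as.integer(tp$labels))))
  expect_error(resample(tp$fa, affine_transform(diag(4)), "cubic"))

  ## trilinear never overshoots the input range
  f <- gwtbss:::random_smooth_field(dim(tp$fa), voxel_size(tp$fa), 3, 8, 7)
  w <- resample(tp$fa, f)
  expect_gte(min(w), 0)
  expect_lte(max(w), max(tp$fa) + 1e-12)
})

test_that("field algebra: composition, inversion, magnitude", {
  tp <- fix_small_template()
  shape <- dim(tp$fa); vs <- voxel_size(tp$fa)
  f <- gwtbss:::random_smooth_field(shape, vs, 3, 8, 11)
  z <- zero_field(shape, vs)
  expect_equal(as.numeric(compose_transforms(z, f)), as.numeric(f),
               tolerance = 1e-6)
  expect_equal(as.numeric(invert_field(z)), as.numeric(z))
  ## invert-compose residual below half a voxel
  res <- compose_transforms(invert_field(f), f)
  expect_lt(deformation_magnitude(res) / mean(vs), 0.5)

  expect_equal(deformation_magnitude(z), 0)
  u <- array(0, c(shape, 3)); u[, , , 1] <- 2
  expect_equal(deformation_magnitude(disp_field(u, vs)), 2)
  ## brute-force recomputation on a random field
  m <- matrix(as.numeric(f), ncol = 3)
  expect_equal(deformation_magnitude(f), mean(sqrt(rowSums(m^2))))
  expect_error(disp_field(array(NA_real_, c(4, 4, 4, 3))), "finite")
})

test_that("composition equals sequential resampling", {
  tp <- fix_small_template()
  shape <- dim(tp$fa); vs <- voxel_size(tp$fa)
  f <- gwtbss:::random_smooth_field(shape, vs, 2, 8, 13)
  M <- diag(4); M[1, 4] <- 1.5; M[2, 4] <- -1
  A <- affine_transform(M)
  seq2 <- resample(resample(tp$fa, A), f)
  comp <- resample(tp$fa, compose_transforms(f, A))
  ## interiors agree to interpolation tolerance (one vs two interpolations)
  core <- as.numeric(tp$fa) > 0.1
  expect_lt(mean(abs(as.numeric(seq2) - as.numeric(comp))[core]), 0.01)
})

test_that("linear registration recovers planted translations", {
  tp <- fix_template()
  M <- diag(4); M[1, 4] <- 3
  shifted <- resample(tp$fa, affine_transform(M))
  tr <- register_linear(shifted, tp$fa, "rigid")
  ## pull-back truth is -3 mm in x
  expect_lt(max(abs(tr$matrix[1:3, 4] - c(-3, 0, 0))), 0.5)
  ## NCC of the returned solution never below the identity's
  ncc_before <- ncc(shifted, tp$fa)
  ncc_after <- ncc(resample(shifted, tr, reference = tp$fa), tp$fa)
  expect_gte(ncc_after, ncc_before)
  ## moving == fixed: identity within a tenth of a voxel
  tr0 <- register_linear(tp$fa, tp$fa, "rigid")
  expect_lt(max(abs(tr0$matrix[1:3, 4])), 0.2)
})

test_that("non-rigid registration recovers planted smooth fields", {
  tp <- fix_template()
  f_true <- gwtbss:::random_smooth_field(dim(tp$fa), voxel_size(tp$fa),
                                         4, 8, 42)
  warped <- resample(tp$fa, f_true)
  r0 <- rmse(warped, tp$fa)
  for (alg in c("independent", "pipeline")) {
    F <- register_nonrigid(warped, tp$fa, alg)
    r1 <- rmse(resample(warped, F), tp$fa)
    expect_lt(r1, r0)                       # always improves on baseline
    if (alg == "independent") expect_lte(r1, 0.5 * r0)
  }
  ## identity case: near-zero fields
  for (alg in c("independent", "pipeline")) {
    F0 <- register_nonrigid(tp$fa, tp$fa, alg)
    expect_lt(deformation_magnitude(F0) / mean(voxel_size(tp$fa)), 0.2)
  }
  ## the two algorithms are genuinely distinct code paths
  Fa <- register_nonrigid(warped, tp$fa, "pipeline")
  Fb <- register_nonrigid(warped, tp$fa, "independent")
  expect_gt(mean(abs(as.numeric(Fa) - as.numeric(Fb))), 1e-4)
  expect_error(register_nonrigid(fix_small_template()$fa, tp$fa), "grid")
})

test_that("kernel selection minimises the recomputed RMSE table", {
  tp <- fix_small_template()
  sp <- cohort_spec(4, seed = 3, warp_amplitude = 2, noise_sd = 0.03)
  originals <- lapply(1:4, function(i) make_subject(tp, sp, i)$fa)
  expect_error(select_kernel_width(originals, originals[1:2]), "length")
  expect_equal(as.numeric(select_kernel_width(originals, originals, 1.5)),
               1.5)
  ## identity warp: any smoothing only adds mismatch -> smallest candidate
  sel <- select_kernel_width(originals, originals)
  expect_equal(as.numeric(sel), 0.5)
  ## blurred copies: returned sigma equals the brute-force argmin
  blurred <- lapply(originals, gaussian_smooth, sigma_mm = 1.2)
  cand <- c(0.5, 1, 1.5, 2)
  sel2 <- select_kernel_width(originals, blurred, cand)
  tab <- sapply(cand, function(s) mean(mapply(function(o, b)
    rmse(gaussian_smooth(o, s), b), originals, blurred)))
  expect_equal(as.numeric(sel2), cand[which.min(tab)])
  expect_equal(unname(attr(sel2, "rmse_table")), tab)
})
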