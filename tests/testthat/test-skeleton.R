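test_that("mean FA is the voxel-wise average", {
  tp <- fix_small_template()
  a <- tp$fa
  b <- fa_volume(pmin(unclass(a) + 0.2, 1), voxel_size(a))
  m <- mean_fa(list(a, b))
  expect_equal(as.numeric(m), (as.numeric(a) + as.numeric(b)) / 2)
  expect_equal(as.numeric(mean_fa(list(a, a))), as.numeric(a))
  expect_error(mean_fa(list(a)), "2")
})

test_that("skeletonisation recovers tube centrelines", {
  tp <- fix_template()
  sk <- skeletonize(tp$fa, 0.2)
  expect_true(all(tp$fa[sk$idx] > 0.2))        # subset of FA > threshold
  expect_equal(sqrt(rowSums(sk$directions^2)), rep(1, length(sk$idx)),
               tolerance = 1e-6)
  cl <- do.call(rbind, tp$centrelines)
  clkey <- paste(cl[, 1], cl[, 2], cl[, 3])
  skkey <- paste(sk$coords[, 1], sk$coords[, 2], sk$coords[, 3])
  expect_gte(mean(clkey %in% skkey), 0.9)      # centreline recovery
  d <- apply(sk$coords, 1, function(p) min(sqrt(colSums((t(cl) - p)^2))))
  expect_lte(max(d), 1)                        # no stray skeleton voxels
})

test_that("skeletonisation handles degenerate inputs", {
  flat <- fa_volume(array(0.1, c(32, 32, 32)), 2)
  expect_warning(sk <- skeletonize(flat, 0.2), "empty")
  expect_length(sk$idx, 0)
})

test_that("projection finds shifted tract peaks within its search region", {
  tp <- fix_template()
  sk <- skeletonize(tp$fa, 0.2)
  own <- project(tp$fa, sk, 8)
  expect_true(all(own >= tp$fa[sk$idx] - 1e-12))   # self-projection bound
  expect_identical(project(tp$fa, sk, 0), tp$fa[sk$idx])
  ## peaks shifted one voxel off the skeleton are recovered exactly
  M <- diag(4); M[1, 4] <- voxel_size(tp$fa)[1]
  sh <- resample(tp$fa, affine_transform(M), "nearest")
  pr <- project(sh, sk, 8)
  expect_gte(mean(abs(pr - tp$fa[sk$idx]) <= 0.02), 0.95)
  ## projected values bounded by the subject's global maximum
  expect_lte(max(pr), max(sh))
})

test_that("projection is monotone in the subject values", {
  tp <- fix_small_template()
  sk <- skeletonize(tp$fa, 0.2)
  base <- project(tp$fa, sk, 8)
  up <- fa_volume(pmin(unclass(tp$fa) + 0.05, 1), voxel_size(tp$fa))
  expect_true(all(project(up, sk, 8) >= base - 1e-12))
})

test_that("cohort projection recovers warped-subject centre values", {
  tp <- fix_template()
  sk <- skeletonize(tp$fa, 0.2)
  sp <- cohort_spec(4, seed = 9, warp_amplitude = 3, noise_sd = 0)
  subs <- make_cohort(tp, sp)
  pm <- project_cohort(subs, sk, 8)
  expect_equal(dim(pm), c(4L, length(sk$idx)))
  expect_true(all(pm >= 0 & pm <= 1))
  ## oracle via the ground-truth warp: the subject's tract-centre peak for
  ## skeleton voxel v sits near x* with x* + u(x*) = v; take the max over
  ## the integer voxels adjacent to x* = v - u(v) (small-warp approx)
  co0 <- sk$coords - 1L
  shape <- dim(tp$fa); vs <- voxel_size(tp$fa)
  ## the oracle scans the true cross-section only (phantom tubes run along
  ## y), not along-tract neighbours whose peaks belong to other voxels
  offs <- as.matrix(expand.grid(-1:1, 0, -1:1))
  for (s in c(1, 3)) {
    fa <- as.numeric(subs[[s]]$fa)
    u <- vapply(1:3, function(c.)
      subs[[s]]$field[cbind(sk$coords, c.)], numeric(nrow(co0)))
    xstar <- co0 - sweep(u, 2, vs, "/")
    ref <- rep(-Inf, nrow(co0))
    for (o in seq_len(nrow(offs))) {
      p <- round(xstar) + matrix(offs[o, ], nrow(co0), 3, byrow = TRUE)
      ok <- p[, 1] >= 0 & p[, 2] >= 0 & p[, 3] >= 0 &
        p[, 1] < shape[1] & p[, 2] < shape[2] & p[, 3] < shape[3]
      k <- p[ok, 1] + shape[1] * (p[ok, 2] + shape[2] * p[ok, 3]) + 1
      ref[ok] <- pmax(ref[ok], fa[k])
    }
    expect_gte(mean(abs(pm[s, ] - ref) <= 0.02), 0.95)
  }
})

test_that("SD maps match their closed form", {
  tp <- fix_small_template()
  a <- tp$fa
  b <- unclass(a); b[5, 5, 5] <- b[5, 5, 5] + 0.1
  sdm <- groupwise_sd_map(list(a, fa_volume(b, voxel_size(a))))
  expect_equal(sdm[5, 5, 5], 0.1 / sqrt(2))
  sdm0 <- groupwise_sd_map(list(a, a, a))
  expect_lt(max(sdm0), 1e-7)
})
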