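test_that("template respects its geometric invariants", {
  tp <- make_template(grid_shape = c(48, 48, 48), voxel_size_mm = 2,
                      n_tracts = 3, seed = 1)
  expect_length(tp$centrelines, 3)
  expect_setequal(setdiff(unique(as.integer(tp$labels)), 0L), 1:3)
  expect_true(all(tp$fa >= 0) && all(tp$fa <= 1))
  expect_true(all(tp$fa[tp$ventricle] <= 0.1))
  expect_true(all(tp$fa[tp$labels > 0] > tp$background_fa))
  ## peak >= 0.6 at centrelines, below 0.2 outside the labelled tube
  cl <- do.call(rbind, tp$centrelines)
  expect_true(all(tp$fa[cl] >= 0.6))
  outside <- tp$labels == 0 & !tp$ventricle
  expect_true(mean(tp$fa[outside] < 0.2) > 0.999)
})

test_that("template is deterministic and centrelines are cross-section maxima", {
  tp <- make_template(seed = 1)
  tp2 <- make_template(seed = 1)
  expect_identical(as.numeric(tp$fa), as.numeric(tp2$fa))
  expect_identical(tp$centrelines, tp2$centrelines)
  ## brute-force scan: each centreline voxel carries the maximum FA of its
  ## tract's cross-section
  for (t in seq_along(tp$centrelines)) {
    cl <- tp$centrelines[[t]]
    for (r in seq_len(nrow(cl))) {
      y <- cl[r, 2]
      sl <- tp$fa[, y, ]
      sl[tp$labels[, y, ] != t] <- -Inf
      expect_gte(tp$fa[cl[r, 1], y, cl[r, 3]], max(sl))
    }
  }
})

test_that("template errors name the violated constraint", {
  expect_error(make_template(grid_shape = c(20, 48, 48)), "32")
  expect_error(make_template(n_tracts = 0), "n_tracts")
  expect_error(make_template(n_tracts = 6), "lane spacing")
})

test_that("subjects are deterministic and reproduce through their field", {
  tp <- fix_small_template()
  sp0 <- cohort_spec(3, seed = 5, warp_amplitude = 0, noise_sd = 0)
  s <- make_subject(tp, sp0, 1)
  expect_equal(as.numeric(s$fa), as.numeric(tp$fa))

  sp <- cohort_spec(3, seed = 5, warp_amplitude = 3, noise_sd = 0)
  a <- make_subject(tp, sp, 2)
  b <- make_subject(tp, sp, 2)
  expect_identical(as.numeric(a$fa), as.numeric(b$fa))
  expect_false(identical(as.numeric(a$fa),
                         as.numeric(make_subject(tp, sp, 3)$fa)))
  ## ground-truth field round trip (no noise: exact resampling identity)
  rt <- resample(tp$fa, a$field)
  expect_lt(max(abs(as.numeric(rt) - as.numeric(a$fa))), 0.02)
  ## amplitude bound and value range
  u <- matrix(as.numeric(a$field), ncol = 3)
  expect_lte(max(sqrt(rowSums(u^2))), sp$warp_amplitude + 1e-9)
  noisy <- make_subject(tp, cohort_spec(3, seed = 5, warp_amplitude = 2,
                                        noise_sd = 0.1), 1)
  expect_true(all(noisy$fa >= 0) && all(noisy$fa <= 1))
})

test_that("atrophy expands the ventricle with a positive-divergence field", {
  tp <- fix_small_template()
  expect_error(simulate_atrophy(tp$fa, array(FALSE, dim(tp$fa)), 0.5),
               "empty")
  id <- simulate_atrophy(tp$fa, tp$ventricle, 0)
  expect_equal(as.numeric(id$fa), as.numeric(tp$fa))

  at <- simulate_atrophy(tp$fa, tp$ventricle, 0.6)
  ## count CSF-like voxels in and around the ventricle before and after
  n_before <- sum(tp$fa <= 0.1)
  n_after <- sum(at$fa <= 0.1)
  expect_gt(n_after, n_before)
  ## forward field divergence positive inside the ventricle
  div <- field_divergence(at$forward_field)
  expect_gt(mean(div[tp$ventricle]), 0)
  ## pull-back field reproduces the returned image
  rt <- resample(tp$fa, at$field)
  expect_equal(as.numeric(rt), as.numeric(at$fa))
})

test_that("reduce_fa applies exactly the stated fraction and composes", {
  tp <- fix_small_template()
  m <- tp$labels == 1
  expect_error(reduce_fa(tp$fa, m, 1.2), "fraction")
  expect_equal(as.numeric(reduce_fa(tp$fa, m, 0)), as.numeric(tp$fa))

  const <- fa_volume(array(0.5, dim(tp$fa)), voxel_size(tp$fa))
  red <- reduce_fa(const, m, 0.4)
  expect_true(all(abs(red[m] - 0.3) < 1e-12))
  expect_true(all(red[!m] == 0.5))

  r <- reduce_fa(tp$fa, m, 0.25)
  expect_equal(mean(r[m]), 0.75 * mean(tp$fa[m]))
  expect_equal(r[!m], tp$fa[!m], ignore_attr = TRUE)
  ## mask-partition property: two disjoint masks = their union
  m2 <- tp$labels == 2
  seq_red <- reduce_fa(reduce_fa(tp$fa, m, 0.3), m2, 0.3)
  un_red <- reduce_fa(tp$fa, m | m2, 0.3)
  expect_equal(as.numeric(seq_red), as.numeric(un_red))
})
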