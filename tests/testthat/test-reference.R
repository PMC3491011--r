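test_that("standard-template alignment reduces cohort spread", {
  tp <- fix_small_template()
  sp <- cohort_spec(3, seed = 41, warp_amplitude = 3, noise_sd = 0)
  subs <- make_cohort(tp, sp)
  co <- align_standard(subs, tp$fa)
  expect_s3_class(co, "aligned_cohort")
  expect_equal(co$strategy, "ST")
  expect_length(co$aligned, 3)
  for (v in co$aligned) expect_equal(dim(v), dim(tp$fa))
  ## transforms round-trip: stored aligned images regenerate from natives
  for (i in 1:3) {
    re <- resample(subs[[i]]$fa, co$transforms[[i]], reference = tp$fa)
    expect_equal(as.numeric(re), as.numeric(co$aligned[[i]]))
  }
  ## mean pairwise RMSE shrinks relative to the unaligned cohort
  pair_rmse <- function(vols) {
    mean(c(rmse(vols[[1]], vols[[2]]), rmse(vols[[1]], vols[[3]]),
           rmse(vols[[2]], vols[[3]])))
  }
  expect_lt(pair_rmse(co$aligned), pair_rmse(lapply(subs, `[[`, "fa")))
})

test_that("identical subjects align to the template trivially", {
  tp <- fix_small_template()
  subs <- list(tp$fa, tp$fa)
  co <- align_standard(subs, tp$fa)
  for (v in co$aligned)
    expect_lt(rmse(v, tp$fa), 0.01)
})

test_that("representative selection finds the least-deformed subject", {
  tp <- fix_small_template()
  ## subject 2 IS the template; 1 and 3 are strongly warped copies
  sp <- cohort_spec(3, seed = 43, warp_amplitude = 4, warp_smoothness = 5,
                    noise_sd = 0)
  subs <- list(make_subject(tp, sp, 1)$fa, tp$fa, make_subject(tp, sp, 3)$fa)
  co <- select_representative(subs, template = NULL, pair_level = 2)
  expect_equal(co$representative, 2L)
  expect_equal(co$strategy, "RS")
  ## selected index equals the argmin of the recomputed mean-deformation
  ## table returned by the routine itself
  md <- attr(co, "mean_deformation")
  expect_equal(co$representative, which.min(md))
  expect_error(select_representative(subs[1:2]), "3")
})

test_that("study-specific template is the stage-1 mean", {
  tp <- fix_small_template()
  sp <- cohort_spec(3, seed = 44, warp_amplitude = 2, noise_sd = 0.02)
  subs <- make_cohort(tp, sp)
  co <- build_study_template(subs, tp$fa)
  expect_equal(co$strategy, "SS")
  stage1 <- attr(co, "stage1")
  expect_equal(as.numeric(co$reference), as.numeric(mean_fa(stage1)))
})

test_that("group-wise atlas iterates to a low-variance average", {
  tp <- fix_small_template()
  sp <- cohort_spec(4, seed = 45, warp_amplitude = 3, noise_sd = 0.02)
  subs <- make_cohort(tp, sp)
  sched <- c("rigid", "affine", rep("nonrigid", 3))
  expect_error(build_groupwise_atlas(subs, schedule = c("affine", "rigid")),
               "rigid")
  co <- build_groupwise_atlas(subs, template = tp$fa, schedule = sched,
                              seed = 3)
  expect_equal(co$strategy, "GW")
  tr <- co$trace
  expect_equal(length(tr$variance), length(tr$schedule))
  nr <- which(tr$schedule == "nonrigid")
  ## variance never rises by more than 5% across recorded non-rigid steps
  if (length(nr) > 1) {
    v <- tr$variance[nr]
    expect_true(all(diff(v) <= 0.05 * head(v, -1)))
    expect_lte(v[length(v)], v[1])
  }
  ## all aligned subjects land on the template grid
  for (v in co$aligned) expect_equal(dim(v), dim(tp$fa))

  ## identical subjects: atlas equals the input, variance ~ 0
  same <- list(tp$fa, tp$fa, tp$fa)
  co0 <- build_groupwise_atlas(same, schedule = c("rigid", "affine"),
                               seed = 1)
  expect_lt(max(co0$trace$variance), 1e-5)
  expect_lt(rmse(co0$reference, tp$fa), 0.01)
})

test_that("group-wise atlas is insensitive to its initial subject", {
  tp <- fix_small_template()
  sp <- cohort_spec(4, seed = 46, warp_amplitude = 3, noise_sd = 0.02)
  subs <- make_cohort(tp, sp)
  sched <- c("rigid", "affine", rep("nonrigid", 2))
  a <- build_groupwise_atlas(subs, schedule = sched, seed = 1)
  b <- build_groupwise_atlas(subs, schedule = sched, seed = 4)
  expect_false(a$trace$init_subject == b$trace$init_subject)
  expect_lt(mean(abs(as.numeric(a$reference) - as.numeric(b$reference))),
            0.03)
})

test_that("the strategy dispatcher covers all strategies on one grid", {
  tp <- fix_small_template()
  sp <- cohort_spec(3, seed = 47, warp_amplitude = 2, noise_sd = 0.02)
  subs <- make_cohort(tp, sp)
  for (s in c("st", "none")) {
    co <- build_reference(subs, tp$fa, s)
    expect_equal(grid_shape_test <- dim(co$aligned[[1]]), dim(tp$fa))
  }
})
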