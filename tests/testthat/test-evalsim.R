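test_that("specificity cohort construction matches its contract", {
  tp <- fix_small_template()
  ctrl <- lapply(make_cohort(tp, cohort_spec(3, seed = 51,
                                             warp_amplitude = 2)), `[[`, "fa")
  expect_error(make_specificity_cohort(ctrl, ctrl[1:2]), "equal")
  ## degenerate simulation: targets equal controls
  sc0 <- suppressWarnings(make_specificity_cohort(ctrl, ctrl))
  expect_equal(sc0$kernel_mm, 0.5)                # smallest candidate wins
  for (i in seq_along(ctrl))
    expect_lt(rmse(sc0$warped_controls[[i]], ctrl[[i]]), 0.02)
})

test_that("warping controls to atrophied targets enlarges their ventricles", {
  sc <- fix_spec_cohort()
  ctrl <- lapply(fix_controls(), `[[`, "fa")
  low_before <- mean(sapply(ctrl, function(v) sum(v <= 0.1)))
  low_after <- mean(sapply(sc$warped_controls, function(v) sum(v <= 0.1)))
  expect_gt(low_after, low_before)
  ## chosen kernel minimises the recomputed round-trip RMSE table
  expect_equal(sc$kernel_mm,
               as.numeric(names(which.min(sc$rmse_table))))
})

test_that("specificity reports are internally consistent", {
  rep_st <- fix_spec_report("st")
  expect_s3_class(rep_st, "experiment_report")
  expect_lte(rep_st$n_false_positive_voxels, rep_st$n_skeleton_voxels)
  ## per-tract calls regenerate from the p-map and label intersection
  lab_at <- unclass(fix_template()$labels)[rep_st$skeleton$idx]
  p <- rep_st$stats$p_fwe_decrease
  for (r in seq_len(nrow(rep_st$per_tract))) {
    id <- rep_st$per_tract$tract[r]
    sel <- lab_at == id
    expect_equal(rep_st$per_tract$n_significant_voxels[r],
                 sum(p[sel] < rep_st$alpha))
    expect_equal(rep_st$per_tract$significant[r], any(p[sel] < rep_st$alpha))
  }
})

test_that("sensitivity detections follow the planted reductions", {
  tp <- fix_small_template()
  ctrl <- make_cohort(tp, cohort_spec(6, seed = 52, warp_amplitude = 2,
                                      noise_sd = 0.04))
  expect_error(run_sensitivity(ctrl, tp$fa, tp$labels, fractions = 1.2,
                               strategy = "none"), "fractions")
  rep <- suppressWarnings(
    run_sensitivity(ctrl, tp$fa, tp$labels, fractions = c(0, 0.4),
                    strategy = "none", n_perm = 300, seed = 4,
                    label_warp = "truth"))
  ## 40% reductions are detected in every tract; fraction 0 detects nothing
  expect_true(all(rep$detections[, "0.4"]))
  expect_false(any(rep$detections[, "0"]))
  ## monotone in fraction
  expect_true(all(rep$detections[, "0.4"] >= rep$detections[, "0"]))
})

test_that("Bland-Altman agreement summaries behave on known shifts", {
  tp <- fix_small_template()
  sk <- skeletonize(tp$fa, 0.2)
  pm <- project_cohort(list(tp$fa, tp$fa), sk, 8)
  ba0 <- bland_altman(pm, pm)
  expect_equal(ba0$median_difference, 0)
  expect_true(all(ba0$difference == 0))

  pm2 <- pm - 0.05
  attr(pm2, "coords") <- attr(pm, "coords")
  class(pm2) <- class(pm)
  ba <- bland_altman(pm, pm2)
  expect_equal(ba$median_difference, 0.05)
  ## median equals an independently sorted midpoint
  d <- sort(ba$difference)
  n <- length(d)
  med <- if (n %% 2) d[(n + 1) / 2] else mean(d[n / 2 + 0:1])
  expect_equal(ba$median_difference, med)

  pm3 <- pm
  attr(pm3, "coords") <- attr(pm, "coords") + 1000L
  expect_error(bland_altman(pm, pm3), "empty")
})
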