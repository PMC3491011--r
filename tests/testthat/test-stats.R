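test_that("design validation catches degenerate inputs", {
  expect_error(design_info(rep("a", 4)), "2 levels")
  g <- rep(c("a", "b"), each = 4)
  expect_error(design_info(g, cbind(x = rep(1, 8))), "rank deficient")
  d <- design_info(g, cbind(age = rnorm(8)))
  expect_true(d$has_covariates)
})

test_that("t-statistics match the textbook pooled formula", {
  set.seed(4)
  g <- rep(c("a", "b"), each = 5)
  Y <- matrix(rnorm(10 * 6, 0.4, 0.05), 10, 6)
  pm <- make_1d_projected(Y)
  t_pkg <- tstat_map(pm, design_info(g))
  t_or <- apply(Y, 2, function(y) oracle_pooled_t(y[1:5], y[6:10]))
  expect_equal(t_pkg, t_or, tolerance = 1e-10)

  ## identical groups: t = 0 everywhere
  Y2 <- rbind(Y[1:5, ], Y[1:5, ])
  expect_equal(tstat_map(make_1d_projected(Y2), design_info(g)),
               rep(0, 6))

  ## a covariate orthogonal to group and data leaves the group effect
  ## untouched (t rescales only by the lost residual degree of freedom)
  z <- rnorm(10)
  X0 <- cbind(1, as.numeric(factor(g)) - 1, Y)
  z <- z - X0 %*% solve(crossprod(X0), crossprod(X0, z))
  t_cov <- tstat_map(pm, design_info(g, cbind(z = z)))
  expect_equal(t_cov, t_pkg * sqrt((10 - 3) / (10 - 2)), tolerance = 1e-8)
})

test_that("TFCE matches the worked single-voxel case and a brute oracle", {
  adj0 <- list(adj = integer(0), start = c(0L, 0L))
  expect_equal(tfce(1, adj0, E = 0.5, H = 2, dh = 0.5), 0.625)
  expect_equal(tfce(0, adj0), 0)
  expect_error(tfce(1, adj0, dh = -1), "dh")

  set.seed(7)
  worst <- 0
  for (r in 1:100) {
    nv <- sample(10:50, 1)
    dims <- if (r %% 2) cbind(seq_len(nv), 1L, 1L)       # 1D chain
            else cbind((seq_len(nv) - 1) %% 7 + 1, (seq_len(nv) - 1) %/% 7 + 1, 1L)
    stat <- pmax(rnorm(nv), 0)
    if (max(stat) == 0) stat[1] <- 0.5
    dh <- max(stat) / 29
    adj <- gwtbss:::skeleton_adjacency(dims)
    got <- tfce(stat, adj, 0.5, 2, dh)
    want <- oracle_tfce(stat, dims, 0.5, 2, dh)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-10)
})

test_that("TFCE is monotone under pointwise increase", {
  set.seed(8)
  dims <- cbind(seq_len(30), 1L, 1L)
  adj <- gwtbss:::skeleton_adjacency(dims)
  s <- pmax(rnorm(30), 0)
  dh <- (max(s) + 0.2) / 50
  base <- tfce(s, adj, dh = dh)
  s2 <- s + 0.2 * runif(30)
  expect_true(all(tfce(s2, adj, dh = dh) >= base - 1e-12))
})

test_that("permutation p-values match full enumeration for 4+4 groups", {
  set.seed(2)
  n <- 8; V <- 12
  Y <- matrix(rnorm(n * V, 0.4, 0.05), n, V)
  Y[5:8, 1:4] <- Y[5:8, 1:4] - 0.08
  pm <- make_1d_projected(Y)
  des <- design_info(rep(c("a", "b"), each = 4))
  st <- suppressMessages(permutation_fwe(pm, des, n_permutations = 500,
                                         seed = 9))
  expect_true(st$exact)
  expect_equal(st$n_permutations, 70L)

  ## independent enumerator over all C(8,4) = 70 relabelings
  adj <- gwtbss:::skeleton_adjacency(attr(pm, "coords"))
  t_obs <- tstat_map(pm, des)
  dh <- max(abs(t_obs)) / 100
  cmb <- utils::combn(8, 4)
  for (dir in c(1, -1)) {
    tf_obs <- tfce(dir * t_obs, adj, dh = dh)
    maxs <- apply(cmb, 2, function(g2) {
      gr <- rep("a", 8); gr[g2] <- "b"
      max(tfce(dir * tstat_map(pm, design_info(gr)), adj, dh = dh))
    })
    p_or <- vapply(tf_obs, function(v) mean(maxs >= v - 1e-12), numeric(1))
    got <- if (dir == 1) st$p_fwe_increase else st$p_fwe_decrease
    expect_equal(got, p_or, tolerance = 1e-12)
  }
})

test_that("permutation inference is seeded, bounded and detects effects", {
  set.seed(3)
  n <- 20; V <- 30
  Y <- matrix(rnorm(n * V, 0.4, 0.03), n, V)
  Y[11:20, 1:10] <- Y[11:20, 1:10] - 0.16   # planted 40% reduction
  pm <- make_1d_projected(Y)
  des <- design_info(rep(c("orig", "red"), each = 10))
  a <- permutation_fwe(pm, des, n_permutations = 200, seed = 5)
  b <- permutation_fwe(pm, des, n_permutations = 200, seed = 5)
  expect_identical(a$p_fwe_decrease, b$p_fwe_decrease)
  expect_false(a$exact)
  expect_gte(min(a$p_fwe_decrease), 1 / 201)       # add-one floor
  expect_lt(min(a$p_fwe_decrease), 0.05)           # power on planted effect
  ## voxels away from the planted cluster are null: at most a single
  ## chance call at the 5% family-wise level
  expect_lte(sum(a$p_fwe_decrease[15:30] < 0.05), 1)

  ## permutation distribution invariant to subject ordering
  ord <- c(seq(2, 20, 2), seq(1, 19, 2))
  pm2 <- make_1d_projected(Y[ord, ])
  des2 <- design_info(rep(c("orig", "red"), each = 10)[ord])
  c2 <- permutation_fwe(pm2, des2, n_permutations = 200, seed = 5)
  expect_equal(sort(c2$tstat), sort(a$tstat), tolerance = 1e-10)
})

test_that("Freedman-Lane handles nuisance covariates", {
  set.seed(6)
  n <- 16; V <- 10
  age <- rnorm(n)
  Y <- matrix(0.4 + rnorm(n * V, 0, 0.03), n, V) + outer(age, rep(0.05, V))
  pm <- make_1d_projected(Y)
  des <- design_info(rep(c("a", "b"), each = 8), cbind(age = age))
  st <- permutation_fwe(pm, des, n_permutations = 300, seed = 2)
  expect_gte(min(st$p_fwe_decrease, st$p_fwe_increase), 0.05 / 2)
  st_lab <- permutation_fwe(pm, des, n_permutations = 300, seed = 2,
                            scheme = "labels")
  expect_s3_class(st_lab, "tbss_stats")
})
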