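#' Two-group design with optional nuisance covariates
#'
#' @param group vector of two distinct labels (factor/character/numeric),
#'   one per subject; the first level is the reference group.
#' @param covariates optional data.frame / matrix of numeric nuisance
#'   covariates (e.g. age, gender), one row per subject.
#' @return A `design_info` with the design matrix `X` (intercept, group
#'   indicator, covariates) and the group indicator column index.
#' @export
design_info <- function(group, covariates = NULL) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("group must have exactly 2 levels")
  if (min(table(g)) < 1) stop("both groups must be non-empty")
  ind <- as.numeric(g == levels(g)[2])
  X <- cbind(intercept = 1, group = ind)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != length(g)) stop("covariates must have one row per subject")
    colnames(cv) <- if (!is.null(colnames(cv))) colnames(cv)
                    else paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, group = g, group_col = 2L,
                 levels = levels(g),
                 has_covariates = !is.null(covariates)),
            class = "design_info")
}

## voxel-wise GLM t-statistics for one column of X; Y is n x V
glm_tstats <- function(Y, X, col) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% t(X)           # p x n
  beta <- B %*% Y                # p x V
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  se <- sqrt(pmax(sigma2 * XtXinv[col, col], 0))
  t <- beta[col, ] / se
  t[!is.finite(t)] <- 0
  t
}

#' Voxel-wise group-contrast t-statistics on projected FA
#'
#' Fits the general linear model (intercept + group + covariates) at every
#' skeleton voxel and returns the t-statistic of the group indicator
#' (second group level minus first).
#'
#' @param matrix a `projected_matrix` (subjects x skeleton voxels).
#' @param design a `design_info` with rows matching the matrix subjects.
#' @return Numeric vector of t values, one per skeleton voxel.
#' @export
tstat_map <- function(matrix, design) {
  stopifnot(inherits(design, "design_info"))
  if (nrow(matrix) != nrow(design$X))
    stop("matrix rows (", nrow(matrix), ") do not match design rows (",
         nrow(design$X), ")")
  glm_tstats(unclass(matrix), design$X, design$group_col)
}

## 26-connectivity adjacency (CSR) between skeleton voxels
skeleton_adjacency <- function(coords, connectivity = 26) {
  v <- nrow(coords)
  if (v == 0) return(list(adj = integer(0), start = integer(1)))
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  edges_from <- integer(0); edges_to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nk <- paste(coords[, 1] + offs[o, 1], coords[, 2] + offs[o, 2],
                coords[, 3] + offs[o, 3])
    m <- match(nk, key)
    hit <- which(!is.na(m))
    edges_from <- c(edges_from, hit)
    edges_to <- c(edges_to, m[hit])
  }
  ord <- order(edges_from)
  ef <- edges_from[ord]; et <- edges_to[ord]
  start <- integer(v + 1)
  cnt <- tabulate(ef, nbins = v)
  start <- c(0L, cumsum(cnt))
  list(adj = as.integer(et - 1L), start = as.integer(start))
}

#' Threshold-free cluster enhancement on a skeleton
#'
#' Discrete TFCE: for each voxel, integrates
#' `extent(h)^E * h^H * dh` over thresholds `h = dh, 2dh, ...` up to the map
#' maximum, where `extent(h)` is the size of the connected supra-threshold
#' component containing the voxel, with connectivity restricted to skeleton
#' voxels. Negative stat values contribute nothing (one-sided enhancement).
#'
#' @param stat_values numeric stat map on skeleton voxels.
#' @param skeleton a `skeleton` (or a precomputed adjacency from it).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; default `max(stat)/100`.
#' @param connectivity 26 (default) or 6.
#' @return Numeric vector of enhanced values (>= 0).
#' @export
tfce <- function(stat_values, skeleton, E = 0.5, H = 2, dh = NULL,
                 connectivity = 26) {
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  adj <- if (is.list(skeleton) && !inherits(skeleton, "skeleton")) skeleton
         else skeleton_adjacency(skeleton$coords, connectivity)
  s <- pmax(stat_values, 0)
  mx <- max(s)
  if (mx <= 0) return(numeric(length(s)))
  if (is.null(dh)) dh <- mx / 100
  c_tfce(s, adj$adj, adj$start, E, H, dh)
}

## all distinct two-group relabelings as an n x K sign matrix of group-2
## membership; K = choose(n, n2)
enumerate_relabelings <- function(n, n2) {
  cmb <- combn(n, n2)
  K <- ncol(cmb)
  M <- matrix(0L, n, K)
  for (k in seq_len(K)) M[cmb[, k], k] <- 1L
  M
}

#' Permutation inference with TFCE and FWE correction
#'
#' Permutes group assignment (Freedman-Lane residual permutation when
#' nuisance covariates are present, or raw label permutation), recomputes
#' the TFCE-enhanced group t-map for each permutation, and corrects each
#' voxel by the permutation distribution of the maximum enhanced statistic.
#' One-sided maps are produced for both contrast directions (second group
#' lower / higher than the first). When the number of distinct relabelings
#' does not exceed `n_permutations`, all of them are enumerated exactly and
#' p-values are exact proportions; otherwise `n_permutations` random
#' relabelings are drawn and the add-one estimator
#' `(1 + #{perm >= obs}) / (n_permutations + 1)` is used.
#'
#' @param matrix a `projected_matrix`.
#' @param design a `design_info`.
#' @param n_permutations requested number of permutations (default 5000,
#'   the conventional full-scale setting).
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @param alpha nominal FWE level recorded in the result (default 0.05).
#' @param scheme `"freedman_lane"` (default) or `"labels"`.
#' @param E,H,dh,connectivity TFCE parameters (see [tfce()]).
#' @return A `tbss_stats` object: `tstat` (signed, group2 - group1),
#'   `tfce_increase`/`tfce_decrease`, `p_fwe_increase`/`p_fwe_decrease`,
#'   `n_permutations` (actually used), `exact`, `seed`, `alpha`.
#' @export
permutation_fwe <- function(matrix, design, n_permutations = 5000, seed = 1,
                            alpha = 0.05,
                            scheme = c("freedman_lane", "labels"),
                            E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  scheme <- match.arg(scheme)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  stopifnot(inherits(design, "design_info"))
  Y <- unclass(matrix)
  n <- nrow(Y)
  X <- design$X
  gcol <- design$group_col
  skel <- attr(matrix, "skeleton")
  adj <- skeleton_adjacency(attr(matrix, "coords"), connectivity)

  t_obs <- glm_tstats(Y, X, gcol)
  if (is.null(dh)) {
    mx <- max(abs(t_obs))
    dh_use <- if (mx > 0) mx / 100 else 1
  } else dh_use <- dh
  tf_inc <- tfce(t_obs, adj, E, H, dh_use, connectivity)
  tf_dec <- tfce(-t_obs, adj, E, H, dh_use, connectivity)

  n2 <- sum(design$X[, gcol] == 1)
  K <- choose(n, n2)
  exact <- K <= n_permutations
  if (exact) {
    relab <- enumerate_relabelings(n, n2)
    B <- ncol(relab)
    message("exact enumeration over ", B, " distinct relabelings")
  } else {
    set.seed(seed)
    B <- n_permutations
  }

  ## Freedman-Lane: fit the nuisance-only model once, permute its residuals
  if (scheme == "freedman_lane" && design$has_covariates) {
    Z <- X[, -gcol, drop = FALSE]
    Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
    Yfit <- Hz %*% Y
    Yres <- Y - Yfit
  }

  max_inc <- numeric(B); max_dec <- numeric(B)
  for (b in seq_len(B)) {
    if (exact) {
      gperm <- relab[, b]
      perm <- NULL
    } else {
      perm <- sample.int(n)
      gperm <- X[perm, gcol]
    }
    if (scheme == "freedman_lane" && design$has_covariates) {
      ## for exact enumeration, realise the relabeling as a deterministic
      ## row permutation of the nuisance residuals
      pidx <- if (exact) relabel_to_perm(X[, gcol], gperm) else perm
      Yb <- Yfit + Yres[pidx, , drop = FALSE]
      Xb <- X
      tb <- glm_tstats(Yb, Xb, gcol)
    } else {
      Xb <- X
      Xb[, gcol] <- gperm
      ok <- qr(Xb)$rank == ncol(Xb)
      tb <- if (ok) glm_tstats(Y, Xb, gcol) else rep(0, ncol(Y))
    }
    max_inc[b] <- max(tfce(tb, adj, E, H, dh_use, connectivity))
    max_dec[b] <- max(tfce(-tb, adj, E, H, dh_use, connectivity))
  }

  if (exact) {
    p_inc <- vapply(tf_inc, function(v) mean(max_inc >= v - 1e-12), numeric(1))
    p_dec <- vapply(tf_dec, function(v) mean(max_dec >= v - 1e-12), numeric(1))
  } else {
    p_inc <- vapply(tf_inc, function(v)
      (1 + sum(max_inc >= v - 1e-12)) / (B + 1), numeric(1))
    p_dec <- vapply(tf_dec, function(v)
      (1 + sum(max_dec >= v - 1e-12)) / (B + 1), numeric(1))
  }

  structure(list(tstat = t_obs,
                 tfce_increase = tf_inc, tfce_decrease = tf_dec,
                 p_fwe_increase = p_inc, p_fwe_decrease = p_dec,
                 perm_max_increase = max_inc, perm_max_decrease = max_dec,
                 n_permutations = B, exact = exact, seed = seed,
                 alpha = alpha, scheme = scheme,
                 skeleton = skel, coords = attr(matrix, "coords")),
            class = "tbss_stats")
}

## map an observed binary labeling to a permutation of subject indices that
## realises it (deterministic: fill positions in order)
relabel_to_perm <- function(g_obs, g_new) {
  idx0 <- which(g_obs == 0); idx1 <- which(g_obs == 1)
  p <- integer(length(g_obs))
  p[g_new == 0] <- idx0
  p[g_new == 1] <- idx1
  p
}

#' @export
print.tbss_stats <- function(x, ...) {
  cat(sprintf(
    "<tbss_stats> %d voxels, %d permutations%s, min p (decrease) = %.4g, min p (increase) = %.4g\n",
    length(x$tstat), x$n_permutations, if (x$exact) " (exact)" else "",
    min(x$p_fwe_decrease), min(x$p_fwe_increase)))
  invisible(x)
}
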