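# Shared fixtures, built lazily and cached for the whole test session so
# expensive registrations are not repeated across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_template <- function() fixture("template", function() make_template(seed = 1))

fix_small_template <- function() fixture("template32", function()
  make_template(grid_shape = c(34, 40, 32), n_tracts = 2, seed = 2))

# 10 controls and 10 atrophy-deformed targets: the specificity experiment's
# raw material (shared by the reference, evalsim and acceptance tests)
fix_controls <- function() fixture("controls", function() {
  make_cohort(fix_template(), cohort_spec(10, seed = 21))
})

fix_targets <- function() fixture("targets", function() {
  tp <- fix_template()
  ad <- make_cohort(tp, cohort_spec(10, seed = 22))
  lapply(seq_along(ad), function(i)
    simulate_atrophy(ad[[i]]$fa, tp$ventricle, severity = 0.8,
                     seed = 100 + i, random_amplitude_mm = 3)$fa)
})

fix_spec_cohort <- function() fixture("spec_cohort", function()
  make_specificity_cohort(fix_controls(), fix_targets()))

fix_sens_ladder <- function() fixture("sens_ladder_st", function() {
  tp <- fix_template()
  suppressWarnings(suppressMessages(
    run_sensitivity(fix_controls(), tp$fa, tp$labels,
                    fractions = c(0.1, 0.2, 0.3, 0.4), strategy = "st",
                    alpha = 0.05, n_perm = 500, seed = 13)))
})

fix_spec_report <- function(strategy) {
  fixture(paste0("spec_", strategy), function() {
    sc <- fix_spec_cohort()
    tp <- fix_template()
    suppressWarnings(
      run_specificity(sc$smoothed_controls, sc$warped_controls, strategy,
                      tp$fa, tp$labels, alpha = 0.05, n_perm = 500,
                      seed = 7))
  })
}

# independent per-voxel TFCE oracle: recomputes components at every
# threshold by label propagation (no shared code with the C++ path)
oracle_tfce <- function(stat, coords, E, H, dh, connectivity = 26) {
  s <- pmax(stat, 0)
  n <- length(s)
  out <- numeric(n)
  mx <- max(s)
  if (mx <= 0 || n == 0) return(out)
  nh <- floor(mx / dh + 1e-9)
  for (ih in seq_len(nh)) {
    h <- ih * dh
    ab <- which(s >= h - 1e-12)
    if (!length(ab)) next
    lab <- seq_along(ab)
    co <- coords[ab, , drop = FALSE]
    repeat {
      changed <- FALSE
      for (a in seq_along(ab)) {
        dv <- abs(sweep(co, 2, co[a, ], "-"))
        nb <- if (connectivity == 26) {
          which(apply(dv, 1, max) <= 1)
        } else {
          which(rowSums(dv) <= 1)
        }
        m <- min(lab[nb])
        if (any(lab[nb] != m)) { lab[nb] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    for (l in unique(lab)) {
      m <- lab == l
      out[ab[m]] <- out[ab[m]] + sum(m)^E * h^H * dh
    }
  }
  out
}

# textbook pooled-variance two-sample t (oracle for tstat_map)
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

make_1d_projected <- function(Y) {
  structure(Y, coords = cbind(seq_len(ncol(Y)), 1L, 1L),
            class = c("projected_matrix", "matrix"))
}
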