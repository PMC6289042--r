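# Shared fixture builders. Everything is generated in code at test
# time; sizes are kept desk-scale so the whole suite stays well inside
# its runtime budget.

tiny_config <- function(...) {
  pipeline_config(
    n_subjects = 6, grid_shape = c(10L, 10L, 10L), n_volumes = 120L,
    trials_per_run = 6L, n_runs = 3L, seed = 42L,
    mvpa = list(radius_voxels = 2L, n_perm_chance = 10L,
                min_sphere_voxels = 5L),
    nbs = list(n_regions = 12L, n_perm = 120L),
    group = list(n_perm = 150L), ...)
}

# one subject's mvpa-mode per-run fits on a 12^3 grid
fit_mvpa_subject <- function(seed, pattern_sd = 0, noise_sd = 1,
                             strategy_symmetric = TRUE,
                             grid = c(12L, 12L, 12L), n_volumes = 200L,
                             n_runs = 5L) {
  cfg <- pipeline_config(n_subjects = 1L, grid_shape = grid,
                         n_volumes = n_volumes, n_runs = n_runs,
                         trials_per_run = 12L)
  des <- generate_design(cfg, seed = seed)[[1L]]
  sp <- effect_spec(grid, pattern_sd = pattern_sd, noise_sd = noise_sd,
                    ar1 = 0.2, drift_amplitude = 0.2,
                    strategy_symmetric = strategy_symmetric,
                    seed = seed + 1L)
  vols <- simulate_bold(des, sp, cfg, seed = seed + 2L)
  mask <- phantom_mask(grid)
  fits <- lapply(seq_len(n_runs), function(r) {
    dm <- build_design_matrix(des$events[des$events$run == r, ], "mvpa",
                              tr = cfg$tr_s, n_frames = cfg$n_volumes)
    fit_glm(vols[[r]], dm, mask = mask)
  })
  list(fits = fits, spec = sp, mask = mask, design = des, config = cfg)
}

# independent flood-fill oracle (recursive DFS over an integer stack),
# written without reference to label_clusters
oracle_components <- function(above) {
  d <- dim(above)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  idx <- which(above)
  coords <- arrayInd(idx, d)
  key <- function(p) p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
  for (i in seq_along(idx)) {
    if (seen[idx[i]]) next
    stack <- list(coords[i, ])
    seen[idx[i]] <- TRUE
    sz <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      sz <- sz + 1L
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        q <- p; q[ax] <- q[ax] + dd
        if (q[ax] < 1L || q[ax] > d[ax]) next
        kq <- key(q)
        if (above[kq] && !seen[kq]) {
          seen[kq] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sort(sizes, decreasing = TRUE)
}

# brute-force BH oracle: scan every p as a candidate threshold and keep
# the largest rejection set satisfying the step-up inequality
oracle_bh <- function(p, q) {
  m <- length(p)
  best <- 0L
  for (thr in sort(unique(p))) {
    r <- sum(p <= thr)
    if (thr <= r * q / m) best <- max(best, r)
  }
  p <= if (best > 0) sort(p)[best] else -Inf
}
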