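make_bs_fits <- function(seed = 1) {
  g <- c(8, 8, 8)
  cfg <- pipeline_config(n_subjects = 1, grid_shape = g,
                         n_volumes = 120, trials_per_run = 6,
                         n_runs = 3)
  des <- generate_design(cfg, seed = seed)[[1]]
  sp <- effect_spec(g, pattern_sd = 0, noise_sd = 0.5,
                    drift_amplitude = 0.2)
  vols <- simulate_bold(des, sp, cfg, seed = seed + 1)
  fits <- lapply(1:3, function(r) {
    dm <- build_design_matrix(des$events[des$events$run == r, ],
                              "beta_series", tr = 2, n_frames = 120)
    fit_glm(vols[[r]], dm)
  })
  list(fits = fits, cfg = cfg, g = g)
}

test_that("beta-series extraction means ROIs correctly", {
  bs <- make_bs_fits(seed = 31)
  at <- generate_phantom_atlas(6, bs$g)
  ser <- extract_beta_series(bs$fits, at)
  # 2 regulation trials per condition per run x 3 runs = 6 per condition
  expect_identical(nrow(ser$positive), 6L)
  expect_identical(nrow(ser$negative), 6L)
  expect_identical(ncol(ser$positive), 6L)
  # ROI mean equals an independent voxel-loop average
  fit <- bs$fits[[1]]
  info <- fit$trial_info
  lab2 <- which(at$volume$data == 2)
  tb <- beta_map(fit, info$column[1])
  expect_equal(unname(ser[[info$condition[1]]][1, 2]), mean(tb[lab2]),
               tolerance = 1e-12)
  # constant beta in an ROI gives a constant series entry
  fit2 <- bs$fits[[1]]
  for (cl in info$column) {
    i <- match(cl, fit2$coef_names)
    fit2$betas[, , , i][lab2] <- 7
  }
  ser2 <- extract_beta_series(list(fit2), at)
  expect_true(all(abs(rbind(ser2$positive, ser2$negative)[, 2] - 7) <
                    1e-12))
  expect_error(extract_beta_series(bs$fits,
                                   generate_phantom_atlas(4, c(6, 6, 6))),
               "grid")
})

test_that("full design yields 60 trials per condition across runs", {
  cfg <- pipeline_config(n_subjects = 1)
  des <- generate_design(cfg, seed = 32)[[1]]
  per_run <- lapply(1:5, function(r)
    build_design_matrix(des$events[des$events$run == r, ], "beta_series",
                        tr = 2, n_frames = 380)$trial_info)
  cond <- unlist(lapply(per_run, `[[`, "condition"))
  expect_identical(sum(cond == "positive"), 60L)
  expect_identical(sum(cond == "negative"), 60L)
})

test_that("connectivity matrices are proper correlation matrices", {
  set.seed(33)
  ser <- matrix(rnorm(50 * 6), 50)
  R <- connectivity_matrix(ser)
  expect_equal(diag(R), rep(1, 6))
  expect_equal(R, t(R))
  expect_true(all(R >= -1 & R <= 1))
  # duplicated series: off-diagonal r = 1 for the pair
  dup <- cbind(ser, ser[, 1])
  expect_equal(connectivity_matrix(dup)[1, 7], 1)
  # long independent series: r ~ 0
  long <- matrix(rnorm(10000 * 2), 10000)
  expect_lt(abs(connectivity_matrix(long)[1, 2]), 0.03)
  # planted r = 0.5 at 10^4 trials recovered within sampling error
  bsX <- simulate_beta_series(1, 2, 10000, matrix(c(1, 2), 1),
                              delta_r = 0.3, seed = 3)
  expect_true(abs(cor(bsX[[1]]$positive)[1, 2] - 0.5) < 0.03)
  # zero-variance ROI flagged missing, not 0
  degen <- cbind(ser, 5)
  Rd <- connectivity_matrix(degen)
  expect_true(all(is.na(Rd[7, -7])))
  expect_error(connectivity_matrix(ser[1:2, ]), "at least 3")
})

test_that("NBS finds nothing when conditions are identical", {
  bs <- simulate_beta_series(8, 10, 30, seed = 34)
  A <- lapply(bs, function(s) connectivity_matrix(s$positive))
  res <- nbs(A, A, n_perm = 100, seed = 1)
  expect_identical(nrow(res$components), 0L)
  expect_error(nbs(A[1:4], A[1:4], n_perm = 100), ">= 6")
  expect_error(nbs(A, A, n_perm = 10), ">= 100")
})

test_that("NBS recovers a planted subnetwork with high edge recall", {
  sub <- clique_edges(1:5)
  bs <- simulate_beta_series(20, 15, 60, sub, delta_r = 0.4, seed = 35)
  A <- lapply(bs, function(s) connectivity_matrix(s$positive))
  B <- lapply(bs, function(s) connectivity_matrix(s$negative))
  res <- nbs(A, B, link_alpha = 0.001, n_perm = 1000, alpha = 0.05,
             seed = 36)
  expect_gt(nrow(res$components), 0L)
  expect_true(res$components$significant[1])
  found <- apply(res$component_edges[[1]], 1, paste, collapse = "-")
  planted <- apply(sub, 1, paste, collapse = "-")
  expect_gt(mean(planted %in% found), 0.8)
})

test_that("condition-flip exchangeability negates edge statistics", {
  bs <- simulate_beta_series(8, 8, 30, clique_edges(1:3), delta_r = 0.3,
                             seed = 37)
  A <- lapply(bs, function(s) connectivity_matrix(s$positive))
  B <- lapply(bs, function(s) connectivity_matrix(s$negative))
  fwd <- nbs(A, B, n_perm = 100, seed = 5)
  rev <- nbs(B, A, n_perm = 100, seed = 5)
  expect_equal(fwd$edge_t, -rev$edge_t, tolerance = 1e-10)
})

test_that("BH step-up matches the all-threshold scan oracle", {
  expect_identical(bh_reject(rep(1, 5), 0.05), rep(FALSE, 5))
  # hand-checkable case: thresholds i*q/m = .0125/.025/.0375/.05
  p <- c(0.0001, 0.0002, 0.04, 0.5)
  expect_identical(bh_reject(p, 0.05), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_reject(p, 0.05), oracle_bh(p, 0.05))
  set.seed(38)
  for (i in 1:25) {
    pv <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- sample(c(0.001, 0.01, 0.05, 0.2), 1)
    expect_identical(bh_reject(pv, q), oracle_bh(pv, q))
  }
})

test_that("link-FDR shares the edge-p machinery with NBS", {
  sub <- clique_edges(1:4)
  bs <- simulate_beta_series(15, 10, 50, sub, delta_r = 0.45, seed = 39)
  A <- lapply(bs, function(s) connectivity_matrix(s$positive))
  B <- lapply(bs, function(s) connectivity_matrix(s$negative))
  q <- 0.01
  nb <- nbs(A, B, link_alpha = q, n_perm = 400, seed = 7)
  fd <- link_fdr(A, B, q = q, n_perm = 400, seed = 7)
  # identical p-values enter both procedures
  expect_identical(nb$edge_p, fd$edge_p)
  # at equal thresholds, the NBS supra-threshold set is the candidate
  # set; BH (step-up) can only reject a subset of {p <= q}
  rejected <- which(bh_reject(fd$edge_p, q))
  expect_true(all(rejected %in% which(fd$edge_p <= q)))
  # strong planted effect: FDR recovers most planted edges too
  found <- apply(fd$edges_significant, 1, paste, collapse = "-")
  expect_gt(mean(apply(sub, 1, paste, collapse = "-") %in% found), 0.7)
  expect_true(nrow(fd$components) >= 1)
})
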