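test_that("canonical HRF has the double-gamma shape", {
  tg <- seq(0, 32, by = 0.1)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_equal(tg[which.max(h)], 5.0, tolerance = 0.11)
  expect_lt(abs(h[length(h)]), 0.01)          # tail at 32 s
  expect_error(canonical_hrf(c(-1, 0, 1)), "negative")
})

test_that("high-pass basis column count follows the cutoff formula", {
  expect_identical(ncol(highpass_basis(380, 2)), 11L)  # floor(2*380*2/128)
  expect_identical(ncol(highpass_basis(380, 2, 1e-9)), 0L)
  expect_error(highpass_basis(380, 2, 0), "cutoff")
  # a slow cosine below the cutoff is captured almost perfectly
  B <- highpass_basis(380, 2)
  y <- cos(2 * pi * (0:379) * 2 / 256)        # 1/256 Hz at TR 2
  fit <- lm.fit(cbind(1, B), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.99)
})

make_run <- function(seed = 1, n_volumes = 120) {
  cfg <- pipeline_config(n_subjects = 1, grid_shape = c(6, 6, 6),
                         n_volumes = n_volumes, trials_per_run = 6)
  des <- generate_design(cfg, seed = seed)[[1]]
  list(cfg = cfg, des = des, ev = des$events[des$events$run == 1, ])
}

test_that("design matrices have the prescribed condition columns", {
  r <- make_run()
  uni <- build_design_matrix(r$ev, "univariate", tr = 2, n_frames = 120)
  expect_identical(uni$condition_cols, c("positive", "negative", "now"))
  mv <- build_design_matrix(r$ev, "mvpa", tr = 2, n_frames = 120)
  expect_identical(mv$condition_cols,
                   c("positive_cue1", "positive_cue2",
                     "negative_cue1", "negative_cue2"))
  expect_true("now" %in% colnames(mv$X))      # now modeled as nuisance
  bs <- build_design_matrix(r$ev, "beta_series", tr = 2, n_frames = 120)
  # one column per regulation trial: 4 of the 6 trials here
  expect_identical(length(bs$condition_cols),
                   sum(r$ev$condition != "now"))
  expect_identical(bs$trial_info$condition,
                   r$ev$condition[r$ev$condition != "now"])
  # full-scale run: 24 regulation trials -> 24 trial columns
  full <- make_run(seed = 2, n_volumes = 120)
  expect_error(build_design_matrix(full$ev, "univariate", tr = 2,
                                   n_frames = 30), "beyond run end")
  expect_error(build_design_matrix(r$ev, "univariate", tr = 2,
                                   n_frames = 120,
                                   motion = matrix(0, 120, 3)), "x 6")
  # shared nuisance set present in all modes
  for (dm in list(uni, mv, bs))
    expect_true(all(c("rating", "iti", "constant") %in% colnames(dm$X)))
})

test_that("full-size mvpa model carries exactly 4 strategy regressors", {
  cfg <- pipeline_config(n_subjects = 1, grid_shape = c(6, 6, 6))
  des <- generate_design(cfg, seed = 3)[[1]]
  dm <- build_design_matrix(des$events[des$events$run == 1, ], "mvpa",
                            tr = 2, n_frames = 380)
  expect_identical(length(dm$condition_cols), 4L)
  bs <- build_design_matrix(des$events[des$events$run == 1, ],
                            "beta_series", tr = 2, n_frames = 380)
  expect_identical(length(bs$condition_cols), 24L)
})

test_that("fit_glm recovers planted betas and the AR(1) coefficient", {
  r <- make_run(seed = 4)
  g <- c(6, 6, 6)
  # noiseless: machine-precision recovery (tested in test-synthetic too,
  # here for the whitened path with motion included)
  sp <- effect_spec(g, amp_regulation = 1.5, amp_now = 0.7,
                    pattern_sd = 0, noise_sd = 0, drift_amplitude = 0)
  v <- simulate_bold(r$des, sp, r$cfg, seed = 1, runs = 1)[[1]]
  mot <- matrix(rnorm(120 * 6, 0, 0.01), 120, 6)
  dm <- build_design_matrix(r$ev, "univariate", tr = 2, n_frames = 120,
                            motion = mot)
  fit <- fit_glm(v, dm)
  vox <- which(sp$univariate$positive$mask)[1]
  expect_equal(beta_map(fit, "positive")[vox], 1.5, tolerance = 1e-7)

  # white noise: rho-hat near zero; AR(0.4): rho-hat in [0.3, 0.5]
  cfg <- pipeline_config(n_subjects = 1, grid_shape = g)
  des <- generate_design(cfg, seed = 5)[[1]]
  for (rho in c(0, 0.4)) {
    spn <- effect_spec(g, amp_regulation = 0.5, amp_now = 0.5,
                       pattern_sd = 0, noise_sd = 1, ar1 = rho,
                       drift_amplitude = 0.3)
    vn <- simulate_bold(des, spn, cfg, seed = 6, runs = 1)[[1]]
    dmn <- build_design_matrix(des$events[des$events$run == 1, ],
                               "univariate", tr = 2, n_frames = 380)
    fn <- fit_glm(vn, dmn)
    if (rho == 0) expect_lt(abs(fn$rho), 0.05)
    else expect_true(fn$rho > 0.3 && fn$rho < 0.5)
    # whitening efficacy: residual lag-1 autocorrelation ~ 0
    expect_lt(abs(fn$rho_whitened), 0.05)
  }
  v_short <- brain_volume(v$data[, , , 1:100], v$voxel_size_mm, v$tr_s)
  expect_error(fit_glm(v_short, dm), "rows")
  dup <- dm; dup$X <- cbind(dm$X, dm$X[, 1])
  expect_error(fit_glm(v, dup), "rank deficient")
})

test_that("nuisance columns with no planted signal leave betas unchanged", {
  r <- make_run(seed = 7)
  sp <- effect_spec(c(6, 6, 6), amp_regulation = 1, amp_now = 0.4,
                    pattern_sd = 0, noise_sd = 0, drift_amplitude = 0)
  v <- simulate_bold(r$des, sp, r$cfg, seed = 1, runs = 1)[[1]]
  dm_full <- build_design_matrix(r$ev, "univariate", tr = 2,
                                 n_frames = 120)
  dm_lean <- dm_full
  keep <- !colnames(dm_full$X) %in% c("rating", "iti")
  dm_lean$X <- dm_full$X[, keep]
  b_full <- fit_glm(v, dm_full)
  b_lean <- fit_glm(v, dm_lean)
  vox <- which(sp$univariate$positive$mask)
  expect_equal(beta_map(b_full, "positive")[vox],
               beta_map(b_lean, "positive")[vox], tolerance = 1e-6)
})

test_that("contrast maps behave under planted, zero and null inputs", {
  r <- make_run(seed = 8)
  g <- c(6, 6, 6)
  sp <- effect_spec(g, amp_regulation = 1, amp_now = 0, pattern_sd = 0,
                    noise_sd = 0, drift_amplitude = 0)
  v <- simulate_bold(r$des, sp, r$cfg, seed = 1, runs = 1)[[1]]
  dm <- build_design_matrix(r$ev, "univariate", tr = 2, n_frames = 120)
  fit <- fit_glm(v, dm)
  con <- compute_contrast(fit, c(positive = 0.5, negative = 0.5,
                                 now = -1))
  expect_gt(mean(con$effect[sp$univariate$positive$mask]), 0.4)
  zero <- compute_contrast(fit, c(positive = 0, negative = 0))
  expect_true(all(zero$effect == 0) && all(zero$t == 0))
  expect_error(compute_contrast(fit, c(bogus = 1)), "unknown")
  expect_error(compute_contrast(fit, c(1, -1)), "named")

  # null noise: upper tail of the t map matches its t distribution
  spn <- effect_spec(g, amp_regulation = 0, amp_now = 0, pattern_sd = 0,
                     noise_sd = 1, ar1 = 0, drift_amplitude = 0,
                     baseline = 0)
  tvals <- unlist(lapply(1:12, function(s) {
    vn <- simulate_bold(r$des, spn, r$cfg, seed = 100 + s, runs = 1)[[1]]
    cn <- compute_contrast(fit_glm(vn, dm),
                           c(positive = 1, negative = -1))
    as.numeric(cn$t)
  }))
  q95 <- quantile(tvals, 0.95)
  expect_equal(as.numeric(q95), qt(0.95, 120 - ncol(dm$X)),
               tolerance = 0.12)
})

test_that("Gaussian smoothing has the right scale and edge handling", {
  g <- c(15, 15, 15)
  arr <- array(0, g); arr[8, 8, 8] <- 1
  expect_identical(smooth_volume(arr, 0), arr)
  sm <- smooth_volume(arr, 8, voxel_size_mm = c(3, 3, 3))
  prof <- sm[, 8, 8] / max(sm)
  # FWHM 8 mm at 3 mm voxels: half max ~ 4 mm ~ 1.33 voxels from center
  xs <- (seq_len(15) - 8) * 3
  half_lo <- approx(prof[1:8], xs[1:8], xout = 0.5, ties = "ordered")$y
  half_hi <- approx(rev(prof[8:15]), rev(xs[8:15]), xout = 0.5,
                    ties = "ordered")$y
  expect_equal(half_hi - half_lo, 8, tolerance = 0.5)
  # constant volumes stay constant (renormalized edges)
  cst <- smooth_volume(array(3.7, g), 8, voxel_size_mm = c(3, 3, 3))
  expect_equal(as.numeric(cst), rep(3.7, prod(g)), tolerance = 1e-12)
  expect_error(smooth_volume(arr, -1), "negative")
})
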