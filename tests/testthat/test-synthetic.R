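test_that("generated designs realize the study structure", {
  cfg <- pipeline_config(n_subjects = 4)
  des <- generate_design(cfg, seed = 11)
  for (d in des) {
    ev <- d$events
    # 12 trials per condition per run, 60 over the five runs
    tab <- table(ev$condition, ev$run)
    expect_true(all(tab == 12L))
    expect_true(all(table(ev$condition) == 60L))
    # two cues per condition, balanced within run
    for (r in unique(ev$run)) for (cn in unique(ev$condition)) {
      cues <- table(ev$cue_id[ev$run == r & ev$condition == cn])
      expect_equal(as.integer(cues), c(6L, 6L))
    }
    # each stimulus belongs to exactly one condition within subject
    sc <- unique(ev[, c("stimulus_id", "condition")])
    expect_identical(nrow(sc), 36L)
    expect_identical(anyDuplicated(sc$stimulus_id), 0L)
    # onsets increase and the schedule fits the run
    for (r in unique(ev$run)) {
      on <- ev$onset[ev$run == r]
      expect_true(all(diff(on) > 0))
      expect_lte(max(on + ev$duration[ev$run == r]),
                 cfg$n_volumes * cfg$tr_s)
    }
  }
  # stimulus-to-condition assignment rotates across subjects
  m1 <- des[[1]]$stim_map$condition
  m2 <- des[[2]]$stim_map$condition
  expect_false(identical(m1, m2))
  expect_identical(des[[1]]$stim_map$condition, des[[4]]$stim_map$condition)
})

test_that("design generation is seed-deterministic and validates input", {
  cfg <- pipeline_config(n_subjects = 2)
  expect_identical(generate_design(cfg, seed = 5),
                   generate_design(cfg, seed = 5))
  expect_false(identical(generate_design(cfg, seed = 5),
                         generate_design(cfg, seed = 6)))
  expect_error(generate_design(pipeline_config(trials_per_run = 8)),
               "divisible by 3")
  expect_error(generate_design(pipeline_config(trials_per_run = 9)),
               "even")
  expect_error(generate_design(pipeline_config(n_volumes = 100)),
               "overflow")
})

test_that("pseudorandomization bounds same-condition streaks", {
  cfg <- pipeline_config(n_subjects = 3)
  for (seed in 1:3) {
    des <- generate_design(cfg, seed = seed)
    for (d in des) for (r in 1:5) {
      runs <- rle(d$events$condition[d$events$run == r])
      expect_lte(max(runs$lengths), 3L)
    }
  }
})

test_that("phantom atlas partitions the interior into contiguous parcels", {
  at <- generate_phantom_atlas(116, c(30, 30, 30))
  vol <- at$volume$data
  expect_identical(sort(unique(as.integer(vol[vol > 0]))), 1:116)
  expect_equal(sum(at$labels$size_voxels), sum(vol > 0))
  expect_equal(sum(vol > 0), 28^3)                    # interior mask
  expect_true(all(at$labels$size_voxels >= 4L))
  # contiguity: each parcel is one connected component (oracle DFS)
  for (lab in c(1L, 37L, 116L))
    expect_length(oracle_components(vol == lab), 1L)

  one <- generate_phantom_atlas(1, c(8, 8, 8))
  expect_equal(sum(one$volume$data == 1), 6^3)
  expect_error(generate_phantom_atlas(1000, c(6, 6, 6)), "grid too small")
})

test_that("simulated ratings follow the condition means and the scale", {
  cfg <- pipeline_config(n_subjects = 30)
  des <- generate_design(cfg, seed = 3)
  mu <- c(positive = 2.3, negative = 2.0, now = 3.0)
  des <- simulate_ratings(des, mu, sd = 1, seed = 4)
  ev <- do.call(rbind, lapply(des, `[[`, "events"))
  expect_true(all(ev$rating %in% 1:5))
  means <- tapply(ev$rating, ev$condition, mean)
  expect_gt(means["now"], means["positive"])
  expect_gt(means["positive"], means["negative"])

  exact <- simulate_ratings(des[[1]], mu, sd = 0, seed = 1)
  expect_true(all(exact$events$rating ==
                    round(mu[exact$events$condition])))
  expect_error(simulate_ratings(des[[1]], c(positive = 0.5, negative = 2,
                                            now = 3)), "within")
})

test_that("null BOLD is constant and planted effects are exact", {
  g <- c(8, 8, 8)
  cfg <- pipeline_config(n_subjects = 1, grid_shape = g,
                         n_volumes = 120, trials_per_run = 6)
  des <- generate_design(cfg, seed = 1)[[1]]
  sp0 <- effect_spec(g, amp_regulation = 0, amp_now = 0, pattern_sd = 0,
                     noise_sd = 0, drift_amplitude = 0, baseline = 100)
  v0 <- simulate_bold(des, sp0, cfg, seed = 1, runs = 1)[[1]]
  expect_true(all(v0$data == 100))

  sp <- effect_spec(g, amp_regulation = 2, amp_now = 1, pattern_sd = 0.5,
                    noise_sd = 0, ar1 = 0, drift_amplitude = 0)
  v <- simulate_bold(des, sp, cfg, seed = 1, runs = 1)[[1]]
  dm <- build_design_matrix(des$events[des$events$run == 1, ],
                            "univariate", tr = 2, n_frames = 120)
  fit <- fit_glm(v, dm)
  for (cn in c("positive", "negative", "now")) {
    blk <- sp$univariate[[cn]]
    # pattern cube is disjoint from univariate cubes: betas exact there
    vox <- which(blk$mask & !sp$pattern$mask)
    expect_equal(beta_map(fit, cn)[vox],
                 rep(blk$amplitude, length(vox)), tolerance = 1e-8)
  }
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  g <- c(4, 4, 4)
  cfg <- pipeline_config(n_subjects = 1, grid_shape = g,
                         n_volumes = 120, trials_per_run = 6)
  des <- generate_design(cfg, seed = 2)[[1]]
  sp <- effect_spec(g, amp_regulation = 0, amp_now = 0, pattern_sd = 0,
                    noise_sd = 1, ar1 = 0.4, drift_amplitude = 0,
                    baseline = 0)
  v <- simulate_bold(des, sp, cfg, seed = 9, runs = 1)[[1]]
  # 64 voxels x 120 frames of pure noise: ~7600 lagged pairs
  M <- matrix(v$data, prod(g), 120)
  r1 <- mean(apply(M, 1, function(x)
    stats::cor(x[-1], x[-length(x)])))
  expect_equal(r1, 0.4, tolerance = 0.06)
  # marginal SD is the requested one
  expect_equal(mean(apply(M, 1, sd)), 1, tolerance = 0.1)
})

test_that("direct beta-series generator plants the prescribed structure", {
  sub <- clique_edges(1:4)
  bs <- simulate_beta_series(2, 8, 10000, sub, delta_r = 0.3, seed = 5)
  Ra <- cor(bs[[1]]$positive); Rb <- cor(bs[[1]]$negative)
  on_a <- mean(Ra[sub]); on_b <- mean(Rb[sub])
  expect_equal(on_a, 0.5, tolerance = 0.03)   # base 0.2 + delta 0.3
  expect_equal(on_b, 0.2, tolerance = 0.03)
  off <- upper.tri(Ra) & !(row(Ra) <= 4 & col(Ra) <= 4)
  expect_equal(mean(Ra[off]) - mean(Rb[off]), 0, tolerance = 0.03)
  expect_error(simulate_beta_series(2, 1, 10), "at least 2 ROIs")
  expect_error(simulate_beta_series(2, 6, 10, clique_edges(1:6),
                                    delta_r = 0.9),
               "positive definite")
})
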