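#' Run the full analysis pipeline
#'
#' Chains the stages end-to-end on synthetic data:
#' `simulate` -> `glm` -> `mvpa` -> `group` -> `connectivity` ->
#' `behavior`. Every stage reads only files written by earlier stages
#' plus the configuration, so stages can be re-run in isolation; all
#' randomness derives from `config$seed` and a fixed seed reproduces
#' the report bit-identically on one machine. A `log.txt` records the
#' seed and the permutation count of every permutation-based stage.
#'
#' @param config a [pipeline_config].
#' @param out_dir report directory (created if needed).
#' @param stages character vector of stage names or `"all"`.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  config <- validate_config(config)
  all_stages <- c("simulate", "glm", "mvpa", "group", "connectivity",
                  "behavior")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("run_pipeline: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.json"))
  for (st in all_stages[all_stages %in% stages]) {
    fn <- get(paste0("stage_", st), mode = "function")
    .log(out_dir, "stage ", st, " started (seed ", config$seed, ")")
    tryCatch(fn(config, out_dir),
             error = function(e)
               stop("pipeline stage '", st, "' failed: ",
                    conditionMessage(e), call. = FALSE))
    .log(out_dir, "stage ", st, " done")
  }
  invisible(out_dir)
}

.log <- function(out_dir, ...) {
  cat(format(Sys.time(), "%H:%M:%S "), ..., "\n", sep = "",
      file = file.path(out_dir, "log.txt"), append = TRUE)
}

.sub_dir <- function(out_dir, s) {
  p <- file.path(out_dir, sprintf("sub-%02d", s))
  dir.create(p, showWarnings = FALSE)
  p
}

.pipeline_effect_spec <- function(config, atlas) {
  sm <- config$sim
  planted <- clique_edges(seq_len(min(5L, config$nbs$n_regions)))
  effect_spec(config$grid_shape,
              amp_regulation = sm$amp_regulation, amp_now = sm$amp_now,
              pattern_sd = sm$pattern_sd, noise_sd = sm$noise_sd,
              ar1 = sm$ar1, drift_amplitude = sm$drift_amplitude,
              baseline = sm$baseline,
              connectivity = list(atlas = atlas$volume, edges = planted,
                                  delta_r = sm$delta_r, base_r = 0.2,
                                  jitter_sd = 0.5),
              seed = .child_seed(config$seed, 11))
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config, out_dir) {
  designs <- generate_design(config, seed = .child_seed(config$seed, 1))
  designs <- simulate_ratings(designs, config$sim$rating_means,
                              sd = config$sim$rating_sd,
                              seed = .child_seed(config$seed, 2))
  atlas <- generate_phantom_atlas(config$nbs$n_regions, config$grid_shape,
                                  voxel_size_mm = config$voxel_size_mm)
  write_volume(atlas$volume, file.path(out_dir, "atlas.nii"))
  write_tsv(atlas$labels, file.path(out_dir, "atlas_labels.tsv"))
  spec <- .pipeline_effect_spec(config, atlas)
  snap <- spec[c("noise_sd", "ar1", "drift_amplitude", "baseline")]
  snap$planted_subnetwork <- apply(spec$connectivity$edges, 1L, paste,
                                   collapse = "-")
  snap$delta_r <- spec$connectivity$delta_r
  jsonlite::write_json(snap, file.path(out_dir, "effect_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  base <- simulate_baseline_ratings(designs,
                                    seed = .child_seed(config$seed, 3))
  write_tsv(base, file.path(out_dir, "baseline_ratings.tsv"))

  for (s in seq_len(config$n_subjects)) {
    sd_ <- .sub_dir(out_dir, s)
    write_events(designs[[s]]$events, file.path(sd_, "events.tsv"))
    vols <- simulate_bold(designs[[s]], spec, config,
                          seed = .child_seed(config$seed, 100 + s))
    old <- .set_seed(.child_seed(config$seed, 200 + s))
    for (r in seq_len(config$n_runs)) {
      write_volume(vols[[paste0("run", r)]],
                   file.path(sd_, sprintf("bold_run-%d.nii", r)))
      mot <- apply(matrix(stats::rnorm(config$n_volumes * 6L, 0, 0.02),
                          ncol = 6L), 2L, cumsum)
      write_tsv(as.data.frame(mot),
                file.path(sd_, sprintf("motion_run-%d.tsv", r)))
    }
    .restore_seed(old)
  }
  invisible(out_dir)
}

.run_fits <- function(config, out_dir, s, mode) {
  sd_ <- .sub_dir(out_dir, s)
  ev <- read_events(file.path(sd_, "events.tsv"))
  lapply(seq_len(config$n_runs), function(r) {
    vol <- read_volume(file.path(sd_, sprintf("bold_run-%d.nii", r)),
                       require_4d = TRUE)
    mot <- as.matrix(read_tsv(file.path(sd_,
                                        sprintf("motion_run-%d.tsv", r))))
    dm <- build_design_matrix(
      ev[ev$run == r, ], mode = mode, tr = config$tr_s,
      n_frames = config$n_volumes, motion = mot,
      rating_duration_s = config$glm$rating_duration_s,
      highpass_hz = config$glm$highpass_hz)
    fit <- fit_glm(vol, dm, mask = phantom_mask(config$grid_shape))
    fit
  })
}

.contrast_defs <- list(
  regulation_gt_now = c(positive = 0.5, negative = 0.5, now = -1),
  negative_gt_positive = c(negative = 1, positive = -1),
  positive_gt_negative = c(positive = 1, negative = -1))

#' @rdname run_pipeline
#' @export
stage_glm <- function(config, out_dir) {
  g <- config$grid_shape
  for (s in seq_len(config$n_subjects)) {
    sd_ <- .sub_dir(out_dir, s)
    fits_uni <- .run_fits(config, out_dir, s, "univariate")
    for (cn in names(.contrast_defs)) {
      eff <- Reduce(`+`, lapply(fits_uni, function(f)
        compute_contrast(f, .contrast_defs[[cn]])$effect)) /
        length(fits_uni)
      eff <- smooth_volume(eff, config$glm$smooth_fwhm_mm,
                           voxel_size_mm = config$voxel_size_mm)
      write_volume(brain_volume(eff, config$voxel_size_mm),
                   file.path(sd_, sprintf("con_%s.nii", cn)))
    }
    fits_mvpa <- .run_fits(config, out_dir, s, "mvpa")
    pat <- mvpa_pattern_array(fits_mvpa)
    for (r in seq_len(config$n_runs))
      write_volume(brain_volume(array(pat[, , , r, ], c(g, 4L)),
                                config$voxel_size_mm),
                   file.path(sd_, sprintf("mvpa_betas_run-%d.nii", r)))
    fits_bs <- .run_fits(config, out_dir, s, "beta_series")
    for (r in seq_len(config$n_runs)) {
      f <- fits_bs[[r]]
      idx <- match(f$trial_info$column, f$coef_names)
      write_volume(brain_volume(f$betas[, , , idx, drop = FALSE],
                                config$voxel_size_mm),
                   file.path(sd_, sprintf("trial_betas_run-%d.nii", r)))
      write_tsv(f$trial_info,
                file.path(sd_, sprintf("trial_info_run-%d.tsv", r)))
    }
  }
  invisible(out_dir)
}

#' @rdname run_pipeline
#' @export
stage_mvpa <- function(config, out_dir) {
  g <- config$grid_shape
  mask <- phantom_mask(g)
  for (s in seq_len(config$n_subjects)) {
    sd_ <- .sub_dir(out_dir, s)
    pat <- array(NA_real_, c(g, config$n_runs, 4L))
    for (r in seq_len(config$n_runs))
      pat[, , , r, ] <- read_volume(
        file.path(sd_, sprintf("mvpa_betas_run-%d.nii", r)))$data
    acc <- cross_classify_searchlight(
      pat, mask, radius = config$mvpa$radius_voxels,
      min_vox = config$mvpa$min_sphere_voxels, cost = config$mvpa$svc_cost)
    ch <- permutation_chance_map(
      pat, mask, radius = config$mvpa$radius_voxels,
      n_perm = config$mvpa$n_perm_chance,
      seed = .child_seed(config$seed, 300 + s),
      min_vox = config$mvpa$min_sphere_voxels, cost = config$mvpa$svc_cost)
    .log(out_dir, "mvpa sub ", s, ": chance map n_perm=",
         config$mvpa$n_perm_chance, " seed=",
         .child_seed(config$seed, 300 + s))
    for (nm in c("accuracy", "chance")) {
      a <- if (nm == "accuracy") acc$accuracy else ch$accuracy
      write_volume(brain_volume(a, config$voxel_size_mm),
                   file.path(sd_, sprintf("%s.nii", nm)))
    }
    sm <- acc$accuracy
    sm[is.na(sm)] <- 0.5
    sm <- smooth_volume(sm, config$glm$smooth_fwhm_mm,
                        voxel_size_mm = config$voxel_size_mm)
    write_volume(brain_volume(sm, config$voxel_size_mm),
                 file.path(sd_, "accuracy_smoothed.nii"))
    skipped <- which(mask & is.na(acc$accuracy))
    write_tsv(as.data.frame(arrayInd(skipped, g)),
              file.path(sd_, "skipped_centers.tsv"))
  }
  invisible(out_dir)
}

.rating_covariate <- function(config, out_dir) {
  vapply(seq_len(config$n_subjects), function(s) {
    ev <- read_events(file.path(.sub_dir(out_dir, s), "events.tsv"))
    ev <- ev[!is.na(ev$rating), ]
    mean(ev$rating[ev$condition == "positive"]) -
      mean(ev$rating[ev$condition == "negative"])
  }, numeric(1))
}

#' @rdname run_pipeline
#' @export
stage_group <- function(config, out_dir) {
  if (config$n_subjects < 3L)
    stop("insufficient subjects for group inference (need >= 3)")
  atlas <- list(volume = read_volume(file.path(out_dir, "atlas.nii")),
                labels = read_tsv(file.path(out_dir, "atlas_labels.tsv")))
  mask <- phantom_mask(config$grid_shape)
  covar <- .rating_covariate(config, out_dir)
  for (cn in names(.contrast_defs)) {
    maps <- lapply(seq_len(config$n_subjects), function(s)
      read_volume(file.path(.sub_dir(out_dir, s),
                            sprintf("con_%s.nii", cn)))$data)
    res <- fwe_peak_correct(maps, mask, alpha = config$group$alpha,
                            n_perm = config$group$n_perm,
                            seed = .child_seed(config$seed, 400),
                            covariate = covar,
                            voxel_size_mm = config$voxel_size_mm,
                            atlas = atlas)
    .log(out_dir, "group contrast ", cn, ": n_perm=",
         config$group$n_perm, " seed=", .child_seed(config$seed, 400))
    write_tsv(res$peaks, file.path(out_dir,
                                   sprintf("table_%s.tsv", cn)))
  }
  amaps <- lapply(seq_len(config$n_subjects), function(s)
    read_volume(file.path(.sub_dir(out_dir, s),
                          "accuracy_smoothed.nii"))$data)
  cmaps <- lapply(seq_len(config$n_subjects), function(s) {
    ch <- read_volume(file.path(.sub_dir(out_dir, s), "chance.nii"))$data
    ch[is.na(ch)] <- 0.5
    ch
  })
  for (mode in c("theoretical", "empirical")) {
    nullv <- if (mode == "theoretical") 0.5 else
      Reduce(`+`, cmaps) / length(cmaps)
    res <- fwe_peak_correct(amaps, mask, alpha = config$group$alpha,
                            n_perm = config$group$n_perm,
                            seed = .child_seed(config$seed, 401),
                            null_value = nullv, covariate = covar,
                            voxel_size_mm = config$voxel_size_mm,
                            atlas = atlas)
    write_tsv(res$peaks,
              file.path(out_dir, sprintf("table_mvpa_%s.tsv", mode)))
  }
  invisible(out_dir)
}

#' @rdname run_pipeline
#' @export
stage_connectivity <- function(config, out_dir) {
  atlas <- read_volume(file.path(out_dir, "atlas.nii"))
  mats <- list(positive = list(), negative = list())
  for (s in seq_len(config$n_subjects)) {
    sd_ <- .sub_dir(out_dir, s)
    fits <- lapply(seq_len(config$n_runs), function(r) {
      b <- read_volume(file.path(sd_, sprintf("trial_betas_run-%d.nii", r)))
      info <- read_tsv(file.path(sd_, sprintf("trial_info_run-%d.tsv", r)))
      list(betas = b$data, coef_names = info$column, trial_info = info)
    })
    fits <- lapply(fits, function(f) structure(f, class = "beta_maps"))
    ser <- extract_beta_series(fits, atlas)
    for (cn in names(ser)) {
      R <- connectivity_matrix(ser[[cn]])
      mats[[cn]][[s]] <- R
      write_tsv(as.data.frame(R),
                file.path(sd_, sprintf("connectivity_%s.tsv", cn)))
    }
  }
  res <- nbs(mats$positive, mats$negative,
             link_alpha = config$nbs$link_alpha,
             n_perm = config$nbs$n_perm, alpha = config$nbs$alpha,
             seed = .child_seed(config$seed, 500))
  .log(out_dir, "nbs: n_perm=", config$nbs$n_perm, " seed=",
       .child_seed(config$seed, 500))
  write_tsv(res$components, file.path(out_dir, "nbs_components.tsv"))
  write_tsv(data.frame(null_max_size = res$null_max_size),
            file.path(out_dir, "nbs_null_distribution.tsv"))
  fdr <- link_fdr(mats$positive, mats$negative, q = config$nbs$fdr_q,
                  n_perm = config$nbs$n_perm,
                  seed = .child_seed(config$seed, 500))
  write_tsv(as.data.frame(fdr$edges_significant),
            file.path(out_dir, "fdr_edges.tsv"))
  invisible(out_dir)
}

#' @rdname run_pipeline
#' @export
stage_behavior <- function(config, out_dir) {
  evs <- lapply(seq_len(config$n_subjects), function(s)
    list(events = read_events(file.path(.sub_dir(out_dir, s),
                                        "events.tsv"))))
  summ <- ratings_summary(evs)
  main <- rm_anova(summ$means, mauchly_alpha = config$behavior$mauchly_alpha)
  ph <- paired_posthocs(summ$means,
                        family_alpha = config$behavior$family_alpha)
  base <- baseline_check(read_tsv(file.path(out_dir,
                                            "baseline_ratings.tsv")))
  rep_ <- rbind(
    data.frame(effect = "condition (RM-ANOVA)", stat = main$F,
               df1 = main$df_corrected[1], df2 = main$df_corrected[2],
               p = main$p, epsilon_hf = main$epsilon_hf,
               threshold = NA_real_),
    data.frame(effect = "baseline assignment", stat = base$F,
               df1 = base$df[1], df2 = base$df[2], p = base$p_uncorrected,
               epsilon_hf = NA_real_, threshold = NA_real_),
    data.frame(effect = paste("posthoc:", ph$comparison), stat = ph$t,
               df1 = ph$df, df2 = NA_real_, p = ph$p,
               epsilon_hf = NA_real_, threshold = ph$bonferroni_threshold))
  write_tsv(rep_, file.path(out_dir, "behavior_report.tsv"))
  write_tsv(as.data.frame(summ$means),
            file.path(out_dir, "rating_means.tsv"))
  invisible(out_dir)
}
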