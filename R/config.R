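#' Pipeline configuration
#'
#' Builds a full configuration for the end-to-end pipeline with every
#' stage block present and defaults filled. The fixed study parameters
#' default to the acquisition actually used: TR 2 s, 380 volumes per
#' run, 5 runs of 36 trials (12 per condition), 31 subjects. The spatial
#' grid defaults to a desk-scale 20^3 lattice of 3 mm voxels (the
#' acquired 64 x 64 x 33 grid is available by overriding `grid_shape`).
#'
#' @param ... named overrides of top-level fields or whole stage blocks
#'   (`glm`, `mvpa`, `nbs`, `group`, `behavior`, `sim`); within a block,
#'   only the named entries are replaced.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_subjects     = 31L,
    grid_shape     = c(20L, 20L, 20L),
    voxel_size_mm  = c(3, 3, 3),
    tr_s           = 2,
    n_runs         = 5L,
    trials_per_run = 36L,
    n_volumes      = 380L,
    seed           = 1L,
    glm = list(
      highpass_hz       = 1 / 128,
      smooth_fwhm_mm    = 8,
      rating_duration_s = 3),
    mvpa = list(
      radius_voxels      = 3L,
      svc_cost           = 1,
      n_perm_chance      = 100L,
      min_sphere_voxels  = 10L),
    nbs = list(
      n_regions  = 116L,
      link_alpha = 0.001,
      n_perm     = 1000L,
      alpha      = 0.05,
      fdr_q      = 0.001),
    group = list(
      alpha  = 0.05,
      n_perm = 1000L),
    behavior = list(
      family_alpha  = 0.05,
      mauchly_alpha = 0.05),
    sim = list(
      baseline        = 100,
      noise_sd        = 1,
      ar1             = 0.3,
      drift_amplitude = 0.5,
      amp_regulation  = 1,     # % signal, positive & negative regions
      amp_now         = 0.5,
      pattern_sd      = 0.8,   # per-voxel cue-invariant pattern scale
      rating_means    = c(positive = 2.3, negative = 2.0, now = 3.0),
      rating_sd       = 1.0,
      delta_r         = 0.4))
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("pipeline_config: overrides must be named")
    for (k in names(ov)) {
      if (!k %in% names(cfg)) stop("pipeline_config: unknown field '", k, "'")
      if (is.list(cfg[[k]]) && !k %in% c("sim")) {
        cfg[[k]][names(ov[[k]])] <- ov[[k]]
      } else if (k == "sim") {
        cfg$sim[names(ov$sim)] <- ov$sim
      } else {
        cfg[[k]] <- ov[[k]]
      }
    }
  }
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a candidate configuration list.
#' @export
validate_config <- function(cfg) {
  cnt <- c("n_subjects", "n_runs", "trials_per_run", "n_volumes")
  for (k in cnt) {
    cfg[[k]] <- as.integer(cfg[[k]])
    if (is.na(cfg[[k]]) || cfg[[k]] < 1L)
      stop("config: ", k, " must be a count >= 1")
  }
  if (!is.numeric(cfg$tr_s) || cfg$tr_s <= 0) stop("config: tr_s must be > 0")
  cfg$grid_shape <- as.integer(cfg$grid_shape)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stop("config: grid_shape must be 3 counts >= 1")
  for (b in c("glm", "mvpa", "nbs", "group", "behavior", "sim"))
    if (!is.list(cfg[[b]])) stop("config: stage block '", b, "' missing")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a configuration file
#'
#' Configurations serialize to pretty-printed JSON and re-parse
#' losslessly; `read_config` re-validates and fills nothing (a complete
#' block structure is required, which `write_config` guarantees).
#'
#' @param cfg a `pipeline_config`.
#' @param path file path (conventionally `.json`).
#' @export
write_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  # named atomic vectors serialize as JSON objects so names survive
  cfg$sim$rating_means <- as.list(cfg$sim$rating_means)
  jsonlite::write_json(cfg, path, pretty = TRUE, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$sim$rating_means))
    cfg$sim$rating_means <- unlist(cfg$sim$rating_means)
  validate_config(cfg)
}
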