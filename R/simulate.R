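#' Effect specification for the BOLD generator
#'
#' Describes everything the generator plants into synthetic data: where
#' each condition raises the mean signal (univariate regions), where a
#' cue-invariant multivoxel pattern distinguishes the positive from the
#' negative strategy (what the cross-cue searchlight is built to find),
#' an optional condition-dependent connectivity structure driving
#' trial-amplitude jitter, and the noise model (AR(1) coefficient,
#' marginal noise SD, slow cosine drift).
#'
#' Default geometry places three non-overlapping cubes in the grid
#' interior for the condition amplitudes and a fourth cube carrying the
#' strategy pattern (per-voxel weights drawn once, N(0, pattern_sd^2),
#' identical for both cues of a strategy; sign +1 for positive, -1 for
#' negative). `pattern_sd = 0` yields data with no strategy information
#' anywhere: the null world for decoding calibration.
#'
#' @param grid_shape integer length-3.
#' @param amp_regulation amplitude of the positive/negative regions.
#' @param amp_now amplitude of the now region.
#' @param pattern_sd SD of the planted per-voxel pattern weights.
#' @param noise_sd marginal SD of the AR(1) noise.
#' @param ar1 AR(1) coefficient, in \[0, 1).
#' @param drift_amplitude scale of the slow cosine drift.
#' @param baseline constant signal level.
#' @param connectivity optional list (`atlas` volume, `edges` 2-column
#'   matrix of region labels, `delta_r`, `base_r`, `jitter_sd`) enabling
#'   condition-dependent trial-amplitude correlations.
#' @param strategy_symmetric if `TRUE`, the positive and negative
#'   conditions share one region (identical mask and amplitude), so
#'   that with `pattern_sd = 0` the data carry *no* strategy
#'   information whatsoever — the exchangeable null world used to
#'   calibrate decoding chance levels. The default keeps separate
#'   regions (spatially distinct univariate responses are themselves
#'   decodable strategy information).
#' @param seed seed for the pattern weights.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(grid_shape, amp_regulation = 1, amp_now = 0.5,
                        pattern_sd = 0.8, noise_sd = 1, ar1 = 0.3,
                        drift_amplitude = 0.5, baseline = 100,
                        connectivity = NULL, strategy_symmetric = FALSE,
                        seed = 1L) {
  if (ar1 < 0 || ar1 >= 1) stop("effect_spec: ar1 must be in [0, 1)")
  stopifnot(is.finite(amp_regulation), is.finite(amp_now),
            is.finite(pattern_sd), noise_sd >= 0)
  g <- as.integer(grid_shape)
  cube <- function(cf, hw) {
    ctr <- pmax(2L, pmin(g - 1L, round(cf * g)))
    lo <- pmax(2L, ctr - hw); hi <- pmin(g - 1L, ctr + hw)
    m <- array(FALSE, g)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  hw <- max(1L, round(min(g) / 10))
  pos_mask <- cube(c(0.28, 0.28, 0.5), hw)
  neg_mask <- if (strategy_symmetric) pos_mask
              else cube(c(0.72, 0.28, 0.5), hw)
  spec <- list(
    grid_shape = g,
    univariate = list(
      positive = list(mask = pos_mask, amplitude = amp_regulation),
      negative = list(mask = neg_mask, amplitude = amp_regulation),
      now = list(mask = cube(c(0.28, 0.72, 0.5), hw),
                 amplitude = amp_now)),
    pattern = list(mask = cube(c(0.72, 0.72, 0.5), hw), weights = NULL),
    connectivity = connectivity,
    noise_sd = noise_sd, ar1 = ar1,
    drift_amplitude = drift_amplitude, baseline = baseline)
  old <- .set_seed(seed); on.exit(.restore_seed(old))
  npat <- sum(spec$pattern$mask)
  spec$pattern$weights <- stats::rnorm(npat, 0, pattern_sd)
  for (blk in spec$univariate)
    if (!any(blk$mask)) stop("effect_spec: effect region outside grid")
  structure(spec, class = "effect_spec")
}

#' Simulate BOLD runs for one subject
#'
#' Signal model per voxel: baseline + condition regressors (cue+image
#' boxcars convolved with [canonical_hrf]) scaled by the region
#' amplitudes + the cue-invariant strategy pattern times the
#' (positive - negative) regressor + slow cosine drift + stationary
#' AR(1) Gaussian noise with marginal SD `noise_sd`. Rating periods and
#' ITIs carry no signal (their regressors still enter the GLM as
#' nuisance terms downstream). If the effect spec carries a
#' `connectivity` block, per-trial amplitude jitter with the prescribed
#' across-trial ROI correlation structure is added to regulation trials,
#' which is what the beta-series pipeline estimates.
#'
#' @param design one subject design from [generate_design].
#' @param spec an [effect_spec] on the same grid.
#' @param config a [pipeline_config] (TR, volumes, grid).
#' @param seed integer seed.
#' @param runs which runs to simulate (default all).
#' @return named list of 4D [brain_volume], one per run.
#' @export
simulate_bold <- function(design, spec, config, seed = 1L, runs = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  g <- as.integer(config$grid_shape)
  if (!identical(g, spec$grid_shape))
    stop("simulate_bold: effect spec grid does not match config grid")
  n <- config$n_volumes
  tr <- config$tr_s
  if (is.null(runs)) runs <- sort(unique(design$events$run))
  nvox <- prod(g)
  old <- .set_seed(seed); on.exit(.restore_seed(old))

  out <- list()
  for (r in runs) {
    ev <- design$events[design$events$run == r, , drop = FALSE]
    xc <- lapply(.conditions, function(cn) {
      sel <- ev$condition == cn
      .convolved_regressor(ev$onset[sel], ev$duration[sel], tr, n)
    })
    names(xc) <- .conditions

    M <- matrix(spec$baseline, nrow = nvox, ncol = n)
    for (cn in .conditions) {
      blk <- spec$univariate[[cn]]
      vi <- which(blk$mask)
      if (length(vi))
        M[vi, ] <- M[vi, ] + blk$amplitude *
          matrix(xc[[cn]], length(vi), n, byrow = TRUE)
    }
    pv <- which(spec$pattern$mask)
    if (length(pv))
      M[pv, ] <- M[pv, ] + outer(spec$pattern$weights,
                                 xc$positive - xc$negative)

    if (!is.null(spec$connectivity))
      M <- M + t(.trial_jitter(ev, spec$connectivity, tr, n))

    if (spec$drift_amplitude > 0) {
      dct <- highpass_basis(n, tr, cutoff_hz = 3 / (n * tr))
      amps <- matrix(stats::rnorm(nvox * ncol(dct), 0,
                                  spec$drift_amplitude), nvox)
      M <- M + amps %*% t(dct)
    }
    if (spec$noise_sd > 0) {
      rho <- spec$ar1
      innov_sd <- spec$noise_sd * sqrt(1 - rho^2)
      E <- matrix(stats::rnorm(nvox * n, 0, innov_sd), nvox, n)
      E[, 1L] <- stats::rnorm(nvox, 0, spec$noise_sd)  # stationary start
      if (rho > 0)
        for (t in 2:n) E[, t] <- E[, t] + rho * E[, t - 1L]
      M <- M + E
    }
    out[[paste0("run", r)]] <- brain_volume(
      array(M, dim = c(g, n)), voxel_size_mm = config$voxel_size_mm,
      tr_s = tr)
  }
  out
}

# Per-trial ROI amplitude jitter with condition-specific correlation;
# returns an n_frames x nvox matrix of added signal.
.trial_jitter <- function(ev, conn, tr, n) {
  atlas <- conn$atlas$data
  labs <- sort(unique(atlas[atlas > 0]))
  k <- length(labs)
  sig <- .target_correlation(k, match(conn$edges[, 1], labs),
                             match(conn$edges[, 2], labs),
                             conn$delta_r, conn$base_r)
  regu <- which(ev$condition != "now")
  X <- vapply(regu, function(i)
    .convolved_regressor(ev$onset[i], ev$duration[i], tr, n), numeric(n))
  U <- matrix(stats::rnorm(length(regu) * k), length(regu), k)
  pos <- ev$condition[regu] == "positive"
  U[pos, ] <- U[pos, , drop = FALSE] %*% sig$chol_a
  U[!pos, ] <- U[!pos, , drop = FALSE] %*% sig$chol_b
  U <- U * conn$jitter_sd
  L <- matrix(0, length(regu), length(atlas))
  inroi <- atlas > 0
  L[, inroi] <- U[, match(atlas[inroi], labs), drop = FALSE]
  X %*% L
}

# Target correlation matrices for the two conditions: exchangeable
# base_r background, + delta_r on the subnetwork edges in condition A.
.target_correlation <- function(k, ei, ej, delta_r, base_r = 0.2) {
  Sb <- matrix(base_r, k, k); diag(Sb) <- 1
  Sa <- Sb
  for (e in seq_along(ei)) {
    Sa[ei[e], ej[e]] <- Sa[ei[e], ej[e]] + delta_r
    Sa[ej[e], ei[e]] <- Sa[ej[e], ei[e]] + delta_r
  }
  ca <- tryCatch(chol(Sa), error = function(e) NULL)
  cb <- tryCatch(chol(Sb), error = function(e) NULL)
  if (is.null(ca) || is.null(cb))
    stop("target correlation matrix not positive definite ",
         "(delta_r too large for this subnetwork)")
  list(a = Sa, b = Sb, chol_a = ca, chol_b = cb)
}

#' All edges among a node set
#' @param nodes integer node ids.
#' @return 2-column matrix of node pairs (i < j).
#' @export
clique_edges <- function(nodes) {
  if (length(nodes) < 2L) stop("clique_edges: need at least 2 nodes")
  t(utils::combn(sort(nodes), 2L))
}

#' Simulate beta series directly
#'
#' Draws trial-by-ROI beta matrices per subject and condition from
#' multivariate normals whose correlation is an exchangeable `base_r`
#' background everywhere, plus `delta_r` on the given subnetwork edges
#' in the positive condition only. This bypasses BOLD simulation and
#' first-level estimation, giving the network-inference stage a fast,
#' exactly specified input: off-subnetwork edges have identical expected
#' correlation in both conditions.
#'
#' @param n_subjects number of subjects.
#' @param n_rois number of regions (>= 2).
#' @param trials_per_condition trials per condition (rows).
#' @param subnetwork 2-column matrix of ROI index pairs (or `NULL` for a
#'   global null).
#' @param delta_r correlation increment on subnetwork edges in the
#'   positive condition; must keep the target matrix positive definite.
#' @param seed integer seed.
#' @param base_r background correlation.
#' @return list per subject: list(`positive`, `negative`) trial x ROI
#'   matrices.
#' @export
simulate_beta_series <- function(n_subjects, n_rois, trials_per_condition,
                                 subnetwork = NULL, delta_r = 0,
                                 seed = 1L, base_r = 0.2) {
  if (n_rois < 2L)
    stop("simulate_beta_series: need at least 2 ROIs (no edges otherwise)")
  if (is.null(subnetwork))
    subnetwork <- matrix(integer(0), ncol = 2L)
  sig <- .target_correlation(n_rois, subnetwork[, 1], subnetwork[, 2],
                             delta_r, base_r)
  old <- .set_seed(seed); on.exit(.restore_seed(old))
  m <- trials_per_condition
  lapply(seq_len(n_subjects), function(s) {
    list(positive = matrix(stats::rnorm(m * n_rois), m) %*% sig$chol_a,
         negative = matrix(stats::rnorm(m * n_rois), m) %*% sig$chol_b)
  })
}
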