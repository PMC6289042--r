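#' Searchlight sphere offsets
#'
#' All integer offsets (dx, dy, dz) with Euclidean norm <= radius,
#' including the origin; 123 offsets at the default radius 3.
#'
#' @param radius sphere radius in voxels (>= 0).
#' @return integer matrix with columns dx, dy, dz.
#' @export
sphere_offsets <- function(radius = 3) {
  if (radius < 0) stop("sphere_offsets: radius must be >= 0")
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  m <- as.matrix(g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' Train a linear support vector classifier
#'
#' Hard interface over the package's deterministic SMO solver: linear
#' kernel, hinge loss with box constraint C on every dual coefficient.
#' Given identical input order the fit is exactly reproducible.
#'
#' @param x numeric matrix, one pattern per row.
#' @param y labels with exactly two levels.
#' @param cost regularization parameter C (default 1, as in the
#'   decoding analyses).
#' @return a `linear_svc`: weight vector `w`, bias `b`, dual
#'   coefficients, and the label coding used.
#' @export
train_linear_svc <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  lev <- unique(y)
  if (length(lev) != 2L)
    stop("train_linear_svc: need exactly 2 classes, got ", length(lev))
  yy <- ifelse(y == lev[1L], 1L, -1L)
  fit <- .svc_train_cpp(x, as.integer(yy), cost)
  structure(list(w = fit$w, b = fit$b, alpha = fit$alpha,
                 levels = lev, cost = cost), class = "linear_svc")
}

#' @rdname train_linear_svc
#' @param object a `linear_svc`.
#' @param newdata matrix of patterns to classify.
#' @param ... unused.
#' @export
predict.linear_svc <- function(object, newdata, ...) {
  s <- as.matrix(newdata) %*% object$w + object$b
  object$levels[ifelse(s >= 0, 1L, 2L)]
}

#' Stack MVPA beta maps into a pattern array
#'
#' @param fits list of `beta_maps` (one per run) from mvpa-mode
#'   first-level models.
#' @return 5D array (x, y, z, run, condition) with conditions in the
#'   fixed order positive_cue1, positive_cue2, negative_cue1,
#'   negative_cue2.
#' @export
mvpa_pattern_array <- function(fits) {
  cond <- c("positive_cue1", "positive_cue2",
            "negative_cue1", "negative_cue2")
  d <- dim(fits[[1L]]$betas)[1:3]
  arr <- array(NA_real_, dim = c(d, length(fits), 4L))
  for (r in seq_along(fits)) {
    if (!all(cond %in% fits[[r]]$coef_names))
      stop("mvpa_pattern_array: run ", r, " lacks the 4 strategy x cue ",
           "regressors (was the GLM fit in mvpa mode?)")
    for (ci in seq_along(cond))
      arr[, , , r, ci] <- beta_map(fits[[r]], cond[ci])
  }
  arr
}

.check_patterns <- function(patterns) {
  d <- dim(patterns)
  if (length(d) != 5L || d[5L] != 4L)
    stop("searchlight: patterns must be a 5D (x,y,z,run,4) array")
  if (d[4L] < 2L) stop("searchlight: need at least 2 runs for",
                       " leave-one-run-out folds")
  d
}

#' Cross-cue searchlight decoding
#'
#' For every in-mask center voxel, patterns are the per-run beta
#' estimates of the 4 strategy-by-cue regressors over the sphere
#' (radius 3 voxels by default). A linear SVC (C = 1) is trained to
#' discriminate positive vs negative strategy using the patterns of one
#' cue from 4 runs and tested on the patterns of the *other* cue from
#' the held-out run, so only cue-invariant strategy information can
#' support above-chance transfer. Both cue-role assignments are
#' computed and averaged over the 5 x 2 cross-classification steps; the
#' mean accuracy is assigned to the center voxel. Spheres are clipped
#' at the mask; centers with fewer than `min_vox` in-mask voxels are
#' returned as `NA`.
#'
#' @param patterns 5D array from [mvpa_pattern_array].
#' @param mask logical 3D array (default: every finite voxel).
#' @param radius sphere radius in voxels.
#' @param min_vox minimum in-mask sphere size.
#' @param cost SVC regularization parameter.
#' @return an `accuracy_map`: 3D `accuracy` in \[0, 1\] (`NA` outside
#'   mask / skipped centers), `n_folds`, `radius`, `mask`.
#' @export
cross_classify_searchlight <- function(patterns, mask = NULL, radius = 3,
                                       min_vox = 10L, cost = 1) {
  d <- .check_patterns(patterns)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  if (anyNA(patterns[rep(mask, d[4L] * 4L)]))
    stop("cross_classify_searchlight: missing beta values inside mask")
  acc <- .searchlight_cpp(as.numeric(patterns), as.integer(d), mask,
                          sphere_offsets(radius), as.integer(min_vox),
                          cost, matrix(0L, 1L, d[4L]))
  structure(list(accuracy = array(acc[, 1L], d[1:3]), chance = NULL,
                 n_folds = d[4L], radius = radius, mask = mask),
            class = "accuracy_map")
}

#' Voxel-wise empirical chance map by label permutation
#'
#' Re-runs the full cross-cue searchlight under permutations of the
#' strategy labels: for each permutation, each run independently either
#' keeps or swaps its positive/negative assignment (both cues swap
#' together, respecting the cue structure). The per-voxel mean accuracy
#' over permutations is the empirical chance level against which
#' observed accuracies are tested.
#'
#' @inheritParams cross_classify_searchlight
#' @param n_perm number of label permutations (>= 100 recommended;
#'   must be >= 1).
#' @param seed integer seed for the permutation draws.
#' @return an `accuracy_map` whose `accuracy` is the chance map;
#'   `n_perm` recorded.
#' @export
permutation_chance_map <- function(patterns, mask = NULL, radius = 3,
                                   n_perm = 100L, seed = 1L,
                                   min_vox = 10L, cost = 1) {
  d <- .check_patterns(patterns)
  if (n_perm < 1L) stop("permutation_chance_map: n_perm must be >= 1")
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  old <- .set_seed(seed); on.exit(.restore_seed(old))
  flips <- matrix(sample(0:1, n_perm * d[4L], replace = TRUE),
                  nrow = n_perm)
  acc <- .searchlight_cpp(as.numeric(patterns), as.integer(d), mask,
                          sphere_offsets(radius), as.integer(min_vox),
                          cost, flips)
  structure(list(accuracy = array(rowMeans(acc), d[1:3]), chance = NULL,
                 n_folds = d[4L], radius = radius, mask = mask,
                 n_perm = n_perm, seed = seed),
            class = "accuracy_map")
}
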