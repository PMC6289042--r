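#' Group one-sample t map
#'
#' Per-voxel one-sample t statistic of the subject maps against
#' `null_value`. With a covariate, each voxel is regressed on an
#' intercept and the centered covariate and the intercept's t is
#' returned (the covariate-adjusted group mean test); with the
#' covariate identically zero or absent this reduces exactly to the
#' plain one-sample test.
#'
#' @param maps list of 3D arrays (one per subject) or a 4D array with
#'   subjects in the 4th dimension; `null_value` may also be a 3D array
#'   (e.g. an empirical chance map).
#' @param null_value scalar or 3D array subtracted from every subject.
#' @param covariate optional numeric, one value per subject.
#' @param mask optional logical 3D array.
#' @return a `group_map`: `t` (3D), `df`, `n`, `mask`.
#' @export
one_sample_map <- function(maps, null_value = 0, covariate = NULL,
                           mask = NULL) {
  Y <- .stack_maps(maps)
  n <- nrow(Y)
  if (n < 3L) stop("one_sample_map: insufficient subjects (need >= 3)")
  d <- attr(Y, "grid")
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  Y <- sweep(Y, 2L, as.numeric(null_value), check.margin = FALSE)
  if (!is.null(covariate)) {
    if (length(covariate) != n)
      stop("one_sample_map: covariate length must equal subject count")
    cov <- covariate - mean(covariate)
    if (all(cov == 0)) covariate <- NULL
  }
  if (is.null(covariate)) {
    X <- matrix(1, n, 1L)
  } else {
    X <- cbind(1, cov)
  }
  p <- ncol(X)
  xtxi <- chol2inv(chol(crossprod(X)))
  B <- xtxi %*% crossprod(X, Y)
  E <- Y - X %*% B
  sig2 <- colSums(E^2) / (n - p)
  tv <- B[1L, ] / sqrt(sig2 * xtxi[1L, 1L])
  tv[!is.finite(tv)] <- 0
  tv[!as.logical(mask)] <- NA_real_
  structure(list(t = array(tv, d), df = n - p, n = n, mask = mask),
            class = "group_map")
}

.stack_maps <- function(maps) {
  if (is.list(maps)) {
    d <- dim(maps[[1L]])
    Y <- t(vapply(maps, function(m) as.numeric(m), numeric(prod(d))))
  } else {
    dd <- dim(maps)
    if (length(dd) != 4L) stop("maps must be a list of 3D arrays or 4D")
    d <- dd[1:3]
    Y <- t(matrix(maps, prod(d), dd[4L]))
  }
  attr(Y, "grid") <- d
  Y
}

#' Permutation (sign-flip) peak-level FWE correction
#'
#' Nonparametric stand-in for parametric peak-level FWE: under the
#' assumption of a sign-symmetric null, subject maps (after subtracting
#' `null_value`) are randomly sign-flipped, the group t map is
#' recomputed, and the maximum t inside `mask` is collected; the
#' corrected p of any observed peak is the proportion of null maxima at
#' or above it (with the usual +1 correction). Passing an ROI mask
#' gives the small-volume-corrected version. One-sided (positive)
#' peaks, matching directional contrasts.
#'
#' @inheritParams one_sample_map
#' @param alpha family-wise alpha.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @return list: `t_map` (a `group_map`), `threshold` (critical t at
#'   `alpha`), `null_max` (permutation distribution), `peaks`
#'   (data.frame of supra-threshold clusters with corrected peak p),
#'   `alpha`, `n_perm`, `seed`.
#' @export
fwe_peak_correct <- function(maps, mask = NULL, alpha = 0.05,
                             n_perm = 1000L, seed = 1L, null_value = 0,
                             covariate = NULL, voxel_size_mm = c(3, 3, 3),
                             atlas = NULL) {
  Y <- .stack_maps(maps)
  n <- nrow(Y)
  if (n < 3L) stop("fwe_peak_correct: insufficient subjects (need >= 3)")
  d <- attr(Y, "grid")
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (!any(mask)) stop("fwe_peak_correct: empty ROI mask")
  obs <- one_sample_map(maps, null_value, covariate, mask)
  Yc <- sweep(Y, 2L, as.numeric(null_value), check.margin = FALSE)
  Ym <- Yc[, as.logical(mask), drop = FALSE]

  old <- .set_seed(seed); on.exit(.restore_seed(old))
  tstat <- function(M) {
    if (is.null(covariate)) {
      mu <- colMeans(M)
      se <- sqrt((colSums(M^2) - n * mu^2) / (n - 1) / n)
      ifelse(se > 0, mu / se, 0)
    } else {
      gm <- one_sample_map(
        lapply(seq_len(n), function(i) array(M[i, ], c(sum(mask), 1, 1))),
        0, covariate)
      as.numeric(gm$t)
    }
  }
  null_max <- vapply(seq_len(n_perm), function(b) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    max(tstat(s * Ym))
  }, numeric(1))

  threshold <- sort(null_max, decreasing = TRUE)[
    max(1L, floor(alpha * (n_perm + 1)))]
  peaks <- report_clusters(obs$t, threshold, atlas = atlas,
                           voxel_size_mm = voxel_size_mm)
  if (nrow(peaks)) {
    peaks$p_fwe <- vapply(peaks$peak_t, function(tt)
      (1 + sum(null_max >= tt)) / (n_perm + 1), numeric(1))
  } else peaks$p_fwe <- numeric(0)
  list(t_map = obs, threshold = threshold, null_max = null_max,
       peaks = peaks, alpha = alpha, n_perm = n_perm, seed = seed)
}

#' Cluster/peak table of a thresholded map
#'
#' Connected supra-threshold clusters under 6-neighbour (face)
#' connectivity, reported one row per cluster in the layout of the
#' usual activation tables: region label at the peak, cluster size in
#' voxels, peak world coordinates (mm, `voxel_size * 0-based index`),
#' and peak t. Rows are ordered by decreasing cluster size.
#'
#' @param t_map 3D array of statistics.
#' @param threshold scalar; voxels with `t > threshold` enter clusters.
#' @param atlas optional atlas (list from [generate_phantom_atlas] or a
#'   3D label array) for the region column.
#' @param voxel_size_mm voxel size for world coordinates.
#' @return data.frame: region, cluster_size, x_mm, y_mm, z_mm, peak_t.
#' @export
report_clusters <- function(t_map, threshold, atlas = NULL,
                            voxel_size_mm = c(3, 3, 3)) {
  if (!is.finite(threshold)) stop("report_clusters: threshold must be finite")
  d <- dim(t_map)
  above <- !is.na(t_map) & t_map > threshold
  lab <- label_clusters(above)
  empty <- data.frame(region = character(0), cluster_size = integer(0),
                      x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0), peak_t = numeric(0))
  if (max(lab) == 0L) return(empty)
  atlas_arr <- if (is.null(atlas)) NULL
    else if (is.list(atlas) && !is.null(atlas$volume)) atlas$volume$data
    else if (inherits(atlas, "brain_volume")) atlas$data else as.array(atlas)
  atlas_names <- if (is.list(atlas) && !is.null(atlas$labels)) atlas$labels

  rows <- lapply(seq_len(max(lab)), function(cl) {
    vox <- which(lab == cl)
    pk <- vox[which.max(t_map[vox])]
    ijk <- arrayInd(pk, d)
    region <- "unlabeled"
    if (!is.null(atlas_arr)) {
      al <- atlas_arr[pk]
      if (al > 0) {
        region <- if (!is.null(atlas_names))
          atlas_names$name[match(al, atlas_names$label)]
        else paste0("roi_", al)
      }
    }
    data.frame(region = region, cluster_size = length(vox),
               x_mm = (ijk[1] - 1L) * voxel_size_mm[1],
               y_mm = (ijk[2] - 1L) * voxel_size_mm[2],
               z_mm = (ijk[3] - 1L) * voxel_size_mm[3],
               peak_t = t_map[pk])
  })
  out <- do.call(rbind, rows)
  out[order(-out$cluster_size), , drop = FALSE]
}

#' Label connected components of a 3D logical array
#'
#' Flood fill under 6-neighbour face connectivity.
#'
#' @param above logical 3D array.
#' @return integer array, 0 = background, 1..K = component ids.
#' @export
label_clusters <- function(above) {
  d <- dim(above)
  lab <- array(0L, d)
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
              c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  k <- 0L
  todo <- which(above)
  for (start in todo) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(v, d)
      for (m in seq_len(6L)) {
        p <- ijk + nb[m, ]
        if (any(p < 1L) || any(p > d)) next
        w <- p[1] + d[1] * ((p[2] - 1L) + d[2] * (p[3] - 1L))
        if (above[w] && lab[w] == 0L) {
          lab[w] <- k
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}
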