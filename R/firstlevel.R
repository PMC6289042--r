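#' Canonical double-gamma hemodynamic response function
#'
#' The SPM-style canonical HRF: a gamma density peaking at 6 s minus
#' 1/6 of a gamma density peaking at 16 s (both with unit dispersion),
#' rescaled so its maximum is 1. The rescaling constant is computed on a
#' dense internal grid so values do not depend on the caller's grid.
#'
#' @param time_grid nonnegative, increasing times (seconds).
#' @return HRF values at `time_grid`.
#' @export
canonical_hrf <- function(time_grid) {
  if (any(time_grid < 0)) stop("canonical_hrf: negative times")
  if (is.unsorted(time_grid, strictly = TRUE))
    stop("canonical_hrf: time_grid must be strictly increasing")
  raw <- function(t) stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  peak <- max(raw(seq(0, 32, by = 0.01)))
  raw(time_grid) / peak
}

#' Discrete-cosine high-pass drift basis
#'
#' Cosine regressors spanning frequencies below the cutoff; the column
#' count is `floor(2 * n_frames * tr * cutoff_hz)` (the constant term is
#' excluded and supplied separately by the design matrix).
#'
#' @param n_frames number of frames (>= 2).
#' @param tr repetition time (s).
#' @param cutoff_hz high-pass cutoff frequency (default 1/128 Hz).
#' @return matrix `n_frames` x K (K possibly 0), columns `drift1..K`.
#' @export
highpass_basis <- function(n_frames, tr, cutoff_hz = 1 / 128) {
  if (n_frames < 2L) stop("highpass_basis: need at least 2 frames")
  if (cutoff_hz <= 0) stop("highpass_basis: cutoff must be > 0")
  k_max <- floor(2 * n_frames * tr * cutoff_hz)
  n <- n_frames
  B <- matrix(0, nrow = n, ncol = k_max)
  t <- seq_len(n) - 1L
  for (k in seq_len(k_max))
    B[, k] <- sqrt(2 / n) * cos(pi * (2 * t + 1) * k / (2 * n))
  if (k_max > 0) colnames(B) <- paste0("drift", seq_len(k_max))
  B
}

# Boxcar epochs convolved with the canonical HRF, sampled at frame
# onsets. Microtime resolution dt; unit-height boxcars, convolution
# scaled by dt so values approximate the HRF-integral response.
.convolved_regressor <- function(onsets, durations, tr, n_frames, dt = 0.1) {
  run_len <- n_frames * tr
  n_hi <- ceiling(run_len / dt) + 1L
  u <- numeric(n_hi)
  for (i in seq_along(onsets)) {
    a <- max(0L, floor(onsets[i] / dt)) + 1L
    b <- min(n_hi, ceiling((onsets[i] + durations[i]) / dt))
    if (b >= a) u[a:b] <- u[a:b] + 1
  }
  h <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(u, rev(h), type = "open")[seq_len(n_hi)] * dt
  conv[pmin(n_hi, floor((seq_len(n_frames) - 1L) * tr / dt) + 1L)]
}

#' Build a first-level design matrix
#'
#' Three variants share one nuisance set (rating-period regressor, ITI
#' regressor, optional 6 motion regressors, cosine drifts, constant):
#' \describe{
#'   \item{univariate}{3 condition regressors (`positive`, `negative`,
#'     `now`), each spanning the combined cue + image epoch.}
#'   \item{mvpa}{4 strategy-by-cue regressors
#'     (`positive_cue1`, `positive_cue2`, `negative_cue1`,
#'     `negative_cue2`); the now condition is modeled as one further
#'     nuisance column.}
#'   \item{beta_series}{one regressor per regulation trial
#'     (least-squares-all), named `trial_<condition>_<index>`; now
#'     trials collapse to one nuisance column.}
#' }
#'
#' @param events event rows of one run (see [events]); `duration` is the
#'   cue+image epoch length.
#' @param mode one of `"univariate"`, `"mvpa"`, `"beta_series"`.
#' @param tr repetition time (s).
#' @param n_frames frames in the run.
#' @param motion optional `n_frames` x 6 matrix of motion parameters.
#' @param rating_duration_s modeled rating-period length (s).
#' @param highpass_hz drift-basis cutoff.
#' @return a `design_matrix`: list with `X` (named columns),
#'   `condition_cols`, `frame_times`, `mode`, and for beta-series mode
#'   `trial_info` (condition/run/order of each trial column).
#' @export
build_design_matrix <- function(events, mode = c("univariate", "mvpa",
                                                 "beta_series"),
                                tr, n_frames, motion = NULL,
                                rating_duration_s = 3,
                                highpass_hz = 1 / 128) {
  mode <- match.arg(mode)
  run_len <- n_frames * tr
  if (nrow(events) && any(events$onset + events$duration > run_len))
    stop("build_design_matrix: events extend beyond run end")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L || nrow(motion) != n_frames)
      stop("build_design_matrix: motion must be ", n_frames, " x 6")
  }
  reg <- function(sel, ons = events$onset[sel], dur = events$duration[sel])
    .convolved_regressor(ons, dur, tr, n_frames)

  cols <- list(); trial_info <- NULL
  if (mode == "univariate") {
    for (cn in .conditions) cols[[cn]] <- reg(events$condition == cn)
    cond_cols <- .conditions
  } else if (mode == "mvpa") {
    for (cn in c("positive", "negative")) for (q in 1:2)
      cols[[paste0(cn, "_cue", q)]] <-
        reg(events$condition == cn & events$cue_id == q)
    cond_cols <- names(cols)
    cols[["now"]] <- reg(events$condition == "now")
  } else {
    regu <- which(events$condition != "now")
    ord <- regu[order(events$onset[regu])]
    nm <- sprintf("trial_%s_%03d", events$condition[ord], seq_along(ord))
    for (i in seq_along(ord))
      cols[[nm[i]]] <- reg(ord[i])
    cond_cols <- nm
    trial_info <- data.frame(column = nm,
                             condition = events$condition[ord],
                             run = events$run[ord],
                             onset = events$onset[ord])
    cols[["now"]] <- reg(events$condition == "now")
  }

  # nuisance epochs: rating follows the image, ITI fills to next onset
  rate_on <- events$onset + events$duration
  iti_on <- rate_on + rating_duration_s
  iti_end <- c(events$onset[-1L], run_len)
  ok <- iti_end - iti_on > 0
  cols[["rating"]] <- reg(TRUE, rate_on, rep(rating_duration_s, nrow(events)))
  cols[["iti"]] <- reg(TRUE, iti_on[ok], (iti_end - iti_on)[ok])
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (!is.null(motion)) {
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
  }
  X <- cbind(X, highpass_basis(n_frames, tr, highpass_hz),
             constant = rep(1, n_frames))
  structure(list(X = X, condition_cols = cond_cols,
                 frame_times = (seq_len(n_frames) - 1L) * tr,
                 mode = mode, trial_info = trial_info),
            class = "design_matrix")
}

#' Fit a first-level GLM with AR(1) prewhitening
#'
#' Two-pass estimation in the SPM spirit: ordinary least squares, a
#' single AR(1) coefficient pooled over in-mask voxels from the lag-1
#' autocorrelation of the OLS residuals, exact AR(1) square-root
#' whitening of data and design, and a re-fit on the whitened model.
#'
#' @param volume a 4D [brain_volume].
#' @param dm a `design_matrix` from [build_design_matrix].
#' @param mask optional logical 3D array; default all voxels.
#' @return a `beta_maps` object: coefficient array (`x,y,z,coef`),
#'   residual variance map, pooled `rho`, residual df, and the whitened
#'   `(X'X)^{-1}` needed for contrasts.
#' @export
fit_glm <- function(volume, dm, mask = NULL) {
  stopifnot(inherits(volume, "brain_volume"), inherits(dm, "design_matrix"))
  d <- dim(volume$data)
  if (length(d) != 4L) stop("fit_glm: 4D volume required")
  n <- d[4L]
  X <- dm$X
  if (nrow(X) != n)
    stop("fit_glm: design has ", nrow(X), " rows for ", n, " frames")
  p <- ncol(X)
  if (n <= p) stop("fit_glm: fewer frames than design columns")
  if (qr(X)$rank < p) stop("fit_glm: design matrix is rank deficient")
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  vox <- which(mask)
  Y <- t(matrix(volume$data, prod(d[1:3]), n))[, vox, drop = FALSE]

  ols <- function(Xw, Yw) {
    XtXi <- chol2inv(chol(crossprod(Xw)))
    B <- XtXi %*% crossprod(Xw, Yw)
    E <- Yw - Xw %*% B
    list(B = B, E = E, XtXi = XtXi)
  }
  f0 <- ols(X, Y)
  rho_raw <- sum(f0$E[-1L, ] * f0$E[-n, ]) / sum(f0$E^2)
  # OLS residuals are autocorrelation-biased (E[rho_hat] ~ tr(L M)/(n-p)
  # under white noise, with M the residual projector and L the lag-1
  # operator); subtract that null bias so white noise maps to rho ~ 0
  H <- X %*% f0$XtXi %*% t(X)
  bias <- (sum(H[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)]) * -1) /
    (n - p)
  rho <- max(-0.99, min(0.99, rho_raw - bias))
  # exact AR(1) inverse square root: first row scaled, then differences
  Wy <- function(M) {
    out <- M
    out[1L, ] <- M[1L, ] * sqrt(1 - rho^2)
    out[-1L, ] <- M[-1L, , drop = FALSE] - rho * M[-n, , drop = FALSE]
    out
  }
  f1 <- ols(Wy(X), Wy(Y))
  df <- n - p
  sig2 <- colSums(f1$E^2) / df
  rho_w <- sum(f1$E[-1L, ] * f1$E[-n, ]) / sum(f1$E^2)

  beta_arr <- array(NA_real_, dim = c(d[1:3], p),
                    dimnames = list(NULL, NULL, NULL, colnames(X)))
  flat <- matrix(beta_arr, prod(d[1:3]), p)
  flat[vox, ] <- t(f1$B)
  sig_arr <- array(NA_real_, dim = d[1:3]); sig_arr[vox] <- sig2
  structure(list(betas = array(flat, dim = c(d[1:3], p),
                               dimnames = dimnames(beta_arr)),
                 sigma2 = sig_arr, rho = rho, rho_whitened = rho_w,
                 df = df, xtx_inv = f1$XtXi,
                 coef_names = colnames(X), mask = mask,
                 condition_cols = dm$condition_cols,
                 trial_info = dm$trial_info,
                 voxel_size_mm = volume$voxel_size_mm),
            class = "beta_maps")
}

#' Extract one coefficient map
#' @param fit a `beta_maps`.
#' @param name coefficient name.
#' @return 3D array.
#' @export
beta_map <- function(fit, name) {
  i <- match(name, fit$coef_names)
  if (is.na(i)) stop("beta_map: no coefficient '", name, "'")
  fit$betas[, , , i]
}

#' Compute a contrast map
#'
#' @param fit a `beta_maps` from [fit_glm].
#' @param weights named numeric vector of contrast weights over design
#'   columns (unnamed columns get weight 0).
#' @return a `contrast_map`: `effect` and `t` 3D arrays plus `df`.
#' @export
compute_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "beta_maps"))
  if (is.null(names(weights)))
    stop("compute_contrast: weights must be named")
  bad <- setdiff(names(weights), fit$coef_names)
  if (length(bad))
    stop("compute_contrast: unknown design columns: ",
         paste(bad, collapse = ", "))
  w <- stats::setNames(numeric(length(fit$coef_names)), fit$coef_names)
  w[names(weights)] <- weights
  d <- dim(fit$betas)
  flat <- matrix(fit$betas, prod(d[1:3]), d[4L])
  eff <- as.numeric(flat %*% w)
  se <- sqrt(as.numeric(fit$sigma2) * drop(t(w) %*% fit$xtx_inv %*% w))
  tmap <- ifelse(se > 0, eff / se, 0)
  structure(list(effect = array(eff, d[1:3]), t = array(tmap, d[1:3]),
                 df = fit$df, voxel_size_mm = fit$voxel_size_mm),
            class = "contrast_map")
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian with sigma = fwhm / (2 sqrt(2 ln 2)) per axis,
#' converted to voxel units by the voxel size; edge weights are
#' renormalized so a constant image stays constant. 4D inputs are
#' smoothed frame-wise in space.
#'
#' @param v a [brain_volume] (3D or 4D) or a bare 3D array (voxel size
#'   then taken from `voxel_size_mm`).
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_size_mm used only for bare arrays.
#' @return same shape as the input.
#' @export
smooth_volume <- function(v, fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  if (fwhm_mm < 0) stop("smooth_volume: negative fwhm")
  is_vol <- inherits(v, "brain_volume")
  arr <- if (is_vol) v$data else as.array(v)
  vs <- if (is_vol) v$voxel_size_mm else voxel_size_mm
  if (fwhm_mm == 0) return(v)
  sig_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  smat <- function(n, s) {
    if (s <= 0) return(diag(n))
    k <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = s)
    k[abs(outer(seq_len(n), seq_len(n), "-")) > ceiling(4 * s)] <- 0
    k / rowSums(k)
  }
  sm3 <- function(a3) {
    dd <- dim(a3)
    a3 <- array(smat(dd[1], sig_vox[1]) %*% matrix(a3, dd[1]), dd)
    a3 <- aperm(array(smat(dd[2], sig_vox[2]) %*%
                        matrix(aperm(a3, c(2, 1, 3)), dd[2]),
                      dd[c(2, 1, 3)]), c(2, 1, 3))
    aperm(array(smat(dd[3], sig_vox[3]) %*%
                  matrix(aperm(a3, c(3, 1, 2)), dd[3]),
                dd[c(3, 1, 2)]), c(2, 3, 1))
  }
  d <- dim(arr)
  out <- if (length(d) == 3L) sm3(arr) else {
    o <- arr
    for (f in seq_len(d[4L])) o[, , , f] <- sm3(arr[, , , f])
    o
  }
  if (is_vol) { v$data <- out; v } else out
}
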