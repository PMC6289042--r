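#' Extract ROI beta series
#'
#' Collapses trial-wise beta maps to one value per trial and region
#' (the mean over the region's voxels) and groups the resulting series
#' by condition, concatenating runs in trial order. With the default
#' design this yields 60 trials per regulation condition.
#'
#' @param fits list of `beta_maps` from beta-series-mode first-level
#'   models (one per run, carrying `trial_info`).
#' @param atlas an atlas (list from [generate_phantom_atlas], a
#'   [brain_volume], or a 3D integer array) on the same grid.
#' @return list per condition (`positive`, `negative`) of trial x ROI
#'   matrices; ROI columns named by atlas label.
#' @export
extract_beta_series <- function(fits, atlas) {
  atlas_arr <- if (is.list(atlas) && !is.null(atlas$volume))
    atlas$volume$data
  else if (inherits(atlas, "brain_volume")) atlas$data else as.array(atlas)
  labs <- sort(unique(atlas_arr[atlas_arr > 0]))
  if (!length(labs)) stop("extract_beta_series: atlas has no regions")
  vox <- which(atlas_arr > 0)
  fac <- factor(atlas_arr[vox], levels = labs)

  per_run <- lapply(fits, function(fit) {
    info <- fit$trial_info
    if (is.null(info))
      stop("extract_beta_series: fit lacks trial_info ",
           "(use a beta_series-mode design matrix)")
    if (!identical(dim(fit$betas)[1:3], dim(atlas_arr)))
      stop("extract_beta_series: atlas grid does not match beta maps")
    d <- dim(fit$betas)
    flat <- matrix(fit$betas, prod(d[1:3]), d[4L])
    tb <- flat[vox, match(info$column, fit$coef_names), drop = FALSE]
    roi <- rowsum(tb, fac) / as.integer(table(fac))
    list(series = t(roi), cond = info$condition)   # trials x ROI
  })
  series <- do.call(rbind, lapply(per_run, `[[`, "series"))
  cond <- unlist(lapply(per_run, `[[`, "cond"))
  colnames(series) <- sprintf("roi_%03d", labs)
  lapply(stats::setNames(nm = c("positive", "negative")), function(cn)
    series[cond == cn, , drop = FALSE])
}

#' Pearson connectivity matrix of ROI beta series
#'
#' @param series trial x ROI matrix (>= 3 trials).
#' @return symmetric ROI x ROI correlation matrix, unit diagonal;
#'   zero-variance ROIs yield `NA` rows/columns (flagged missing, never
#'   silently 0).
#' @export
connectivity_matrix <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3L)
    stop("connectivity_matrix: need at least 3 trials")
  sds <- apply(series, 2L, stats::sd)
  R <- suppressWarnings(stats::cor(series))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  R
}

# ---- shared edge machinery ------------------------------------------------

# upper-triangle edge index of a k x k matrix
.edge_index <- function(k) {
  ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
}

# Fisher-z paired differences: subjects x edges
.edge_differences <- function(matrices_a, matrices_b) {
  n <- length(matrices_a)
  if (n != length(matrices_b) || n < 6L)
    stop("paired condition matrices required for >= 6 subjects")
  k <- nrow(matrices_a[[1L]])
  ei <- .edge_index(k)
  zt <- function(R) atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, R[ei])))
  D <- t(vapply(seq_len(n), function(s) {
    if (!isTRUE(all.equal(dim(matrices_a[[s]]), c(k, k))) ||
        !isTRUE(all.equal(dim(matrices_b[[s]]), c(k, k))))
      stop("connectivity matrices differ in dimension across subjects")
    zt(matrices_a[[s]]) - zt(matrices_b[[s]])
  }, numeric(nrow(ei))))
  list(D = D, edges = ei, k = k, n = n)
}

# paired t over rows of D under sign patterns S (rows of +/-1)
.flip_t <- function(D, S) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ssq <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  v <- (ssq - n * M^2) / (n - 1)
  T <- M / sqrt(v / n)
  T[!is.finite(T)] <- 0
  T
}

# Pooled permutation p-values: V is (n_perm + 1) x E with the observed
# statistic in row 1. Every element is compared symmetrically against
# the other n_perm elements of its column, so the observed row and each
# permutation row get exchangeable p-values (resolution 1/n_perm,
# minimum 0 for a strict column maximum).
.pooled_perm_p <- function(V) {
  n_tot <- nrow(V)
  P <- apply(abs(V), 2L, function(col)
    (n_tot - rank(col, ties.method = "min")) / (n_tot - 1))
  matrix(P, nrow = n_tot)
}

# connected components of an edge set via union-find;
# returns component id per edge (integer(0) if no edges)
.edge_components <- function(edges) {
  if (nrow(edges) == 0L) return(integer(0))
  nodes <- sort(unique(as.integer(edges)))
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(match(edges[e, 1L], nodes))
    b <- find(match(edges[e, 2L], nodes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(match(edges[, 1L], nodes), find, integer(1))
  as.integer(factor(roots))
}

#' Network-based statistic (NBS)
#'
#' Paired comparison of two condition connectivity matrices per
#' subject. Per edge, correlations are Fisher-z transformed and a
#' paired t statistic of the within-subject difference is computed;
#' edge-level significance comes from the permutation distribution of
#' that edge's statistic under random within-subject condition flips
#' (two-sided). The supra-threshold graph at `link_alpha` is
#' decomposed into connected components whose statistic is their edge
#' count; the same permutations provide the null distribution of the
#' maximal component size, giving each observed component a
#' FWE-corrected p.
#'
#' Edge p-values are pooled-rank permutation p-values with resolution
#' `1/n_perm` (an edge whose observed |t| exceeds every permuted value
#' gets p = 0), so a link threshold of 0.001 is attainable at the 1,000
#' permutations used by default.
#'
#' @param matrices_a,matrices_b lists of per-subject condition
#'   connectivity matrices (same subjects, same order).
#' @param link_alpha edge-level threshold (default 0.001).
#' @param n_perm number of condition-flip permutations (>= 100).
#' @param alpha component-level FWE threshold.
#' @param seed integer seed.
#' @return list: `components` (data.frame: component, n_edges, n_nodes,
#'   p_fwe, significant), `component_edges` (list of edge matrices),
#'   `edge_t`, `edge_p`, `null_max_size`, `edges`, parameters.
#' @export
nbs <- function(matrices_a, matrices_b, link_alpha = 0.001,
                n_perm = 1000L, alpha = 0.05, seed = 1L) {
  if (n_perm < 100L) stop("nbs: n_perm must be >= 100")
  ed <- .edge_differences(matrices_a, matrices_b)
  keep <- !apply(ed$D, 2L, anyNA)   # listwise exclusion of missing edges
  old <- .set_seed(seed); on.exit(.restore_seed(old))
  S <- rbind(rep(1, ed$n),
             matrix(sample(c(-1, 1), n_perm * ed$n, replace = TRUE),
                    n_perm, ed$n))
  Tm <- matrix(0, n_perm + 1L, ncol(ed$D))
  Tm[, keep] <- .flip_t(ed$D[, keep, drop = FALSE], S)
  P <- matrix(1, n_perm + 1L, ncol(ed$D))
  P[, keep] <- .pooled_perm_p(Tm[, keep, drop = FALSE])

  comp_sizes <- function(sel) {
    if (!any(sel)) return(integer(0))
    cid <- .edge_components(ed$edges[sel, , drop = FALSE])
    tabulate(cid)
  }
  null_max <- vapply(seq_len(n_perm) + 1L, function(f) {
    sz <- comp_sizes(P[f, ] < link_alpha)
    if (length(sz)) max(sz) else 0L
  }, integer(1))

  obs_sel <- P[1L, ] < link_alpha
  comps <- data.frame(component = integer(0), n_edges = integer(0),
                      n_nodes = integer(0), p_fwe = numeric(0),
                      significant = logical(0))
  comp_edges <- list()
  if (any(obs_sel)) {
    E <- ed$edges[obs_sel, , drop = FALSE]
    cid <- .edge_components(E)
    for (cl in seq_len(max(cid))) {
      ce <- E[cid == cl, , drop = FALSE]
      p <- (1 + sum(null_max >= nrow(ce))) / (n_perm + 1)
      comps <- rbind(comps, data.frame(
        component = cl, n_edges = nrow(ce),
        n_nodes = length(unique(as.integer(ce))),
        p_fwe = p, significant = p < alpha))
      comp_edges[[cl]] <- ce
    }
    ord <- order(-comps$n_edges)
    comps <- comps[ord, ]; comps$component <- seq_len(nrow(comps))
    comp_edges <- comp_edges[ord]
  }
  list(components = comps, component_edges = comp_edges,
       edge_t = Tm[1L, ], edge_p = P[1L, ], null_max_size = null_max,
       edges = ed$edges, link_alpha = link_alpha, alpha = alpha,
       n_perm = n_perm, seed = seed)
}

#' Benjamini-Hochberg step-up
#'
#' @param p numeric p-values.
#' @param q FDR level.
#' @return logical rejection vector (step-up rule: reject the `i*`
#'   smallest p-values where `i*` is the largest `i` with
#'   `p_(i) <= i q / m`).
#' @export
bh_reject <- function(p, q) {
  m <- length(p)
  if (!m) return(logical(0))
  o <- order(p)
  ok <- p[o] <= seq_len(m) * q / m
  istar <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (istar > 0L) rej[o[seq_len(istar)]] <- TRUE
  rej
}

#' Link-wise FDR on edge permutation p-values
#'
#' Same edge statistics and permutation p-values as [nbs], followed by
#' Benjamini-Hochberg step-up over edges at level `q`; the rejected
#' edge set is additionally decomposed into connected components.
#'
#' @inheritParams nbs
#' @param q FDR level (the study used corrected p < 0.001).
#' @return list: `edges_significant` (edge matrix), `components`
#'   (data.frame component/n_edges/n_nodes), `edge_p`, `edge_t`, `q`.
#' @export
link_fdr <- function(matrices_a, matrices_b, q = 0.001, n_perm = 1000L,
                     seed = 1L) {
  if (n_perm < 100L) stop("link_fdr: n_perm must be >= 100")
  fit <- nbs(matrices_a, matrices_b, link_alpha = q, n_perm = n_perm,
             alpha = 0.05, seed = seed)
  rej <- bh_reject(fit$edge_p, q)
  E <- fit$edges[rej, , drop = FALSE]
  comps <- data.frame(component = integer(0), n_edges = integer(0),
                      n_nodes = integer(0))
  if (nrow(E)) {
    cid <- .edge_components(E)
    comps <- do.call(rbind, lapply(seq_len(max(cid)), function(cl) {
      ce <- E[cid == cl, , drop = FALSE]
      data.frame(component = cl, n_edges = nrow(ce),
                 n_nodes = length(unique(as.integer(ce))))
    }))
  }
  list(edges_significant = E, components = comps, edge_p = fit$edge_p,
       edge_t = fit$edge_t, q = q, n_perm = n_perm, seed = seed)
}
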