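#' Per-subject condition rating summary
#'
#' Mean craving rating per subject and condition; trials without a
#' response (missing rating) are dropped before averaging.
#'
#' @param designs list of subject designs with filled ratings (see
#'   [simulate_ratings]) or one such design.
#' @return list: `means` (subjects x 3 conditions matrix), `counts`.
#' @export
ratings_summary <- function(designs) {
  if (!is.null(designs$events)) designs <- list(designs)
  means <- t(vapply(designs, function(d) {
    ev <- d$events[!is.na(d$events$rating), , drop = FALSE]
    vapply(.conditions, function(cn)
      mean(ev$rating[ev$condition == cn]), numeric(1))
  }, numeric(3)))
  counts <- t(vapply(designs, function(d) {
    ev <- d$events[!is.na(d$events$rating), , drop = FALSE]
    vapply(.conditions, function(cn)
      sum(ev$condition == cn), numeric(1))
  }, numeric(3)))
  colnames(means) <- colnames(counts) <- .conditions
  if (any(!is.finite(means)))
    stop("ratings_summary: a subject has no rated trials in some condition")
  list(means = means, counts = counts)
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Within-subject one-way ANOVA on a subjects x conditions matrix.
#' Mauchly's test of sphericity is run on the orthonormalized contrast
#' covariance; when its p-value falls below `mauchly_alpha` the
#' Huynh-Feldt epsilon (clipped at 1) rescales both degrees of freedom
#' before the F p-value is computed. Two-condition input degenerates to
#' the paired t-test (F = t^2, epsilon = 1 by construction).
#'
#' @param y numeric matrix, one row per subject, one column per
#'   condition (no missing cells).
#' @param mauchly_alpha trigger for applying the correction.
#' @return list: `F`, `df` (uncorrected pair), `df_corrected`,
#'   `p_uncorrected`, `p` (the reported p, corrected when triggered),
#'   `epsilon_hf`, `epsilon_gg`, `mauchly_w`, `mauchly_p`,
#'   `sphericity_violated`, `n`, `k`.
#' @export
rm_anova <- function(y, mauchly_alpha = 0.05) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  if (anyNA(y)) stop("rm_anova: missing cells are not allowed")
  if (n < 3L) stop("rm_anova: need at least 3 subjects")
  if (k < 2L) stop("rm_anova: need at least 2 conditions")

  gm <- mean(y)
  ss_cond <- n * sum((colMeans(y) - gm)^2)
  ss_subj <- k * sum((rowMeans(y) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fval <- if (ss_err <= .Machine$double.eps * ss_tot && ss_cond == 0) 0 else
    (ss_cond / df1) / (ss_err / df2)
  if (!is.finite(Fval)) Fval <- 0

  if (k == 2L) {
    d <- y[, 1L] - y[, 2L]
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    Fval <- tt^2
    p <- 2 * stats::pt(-abs(tt), n - 1)
    return(list(F = Fval, df = c(df1, df2), df_corrected = c(df1, df2),
                p_uncorrected = p, p = p, epsilon_hf = 1, epsilon_gg = 1,
                mauchly_w = 1, mauchly_p = NA_real_,
                sphericity_violated = FALSE, n = n, k = k))
  }

  # orthonormal contrasts of the condition space
  C <- qr.Q(qr(stats::contr.helmert(k)))
  Z <- y %*% C                          # n x (k-1)
  S <- stats::cov(Z)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  q <- k - 1
  W <- if (mean(lam) > 0) prod(lam) / mean(lam)^q else 1
  # two-term asymptotic null distribution of -n rho log W (as in the
  # standard Mauchly test implementation)
  ndf <- n - 1
  f <- 1 - (2 * q^2 + q + 2) / (6 * q * ndf)
  chi <- if (W > 0) -ndf * f * log(W) else Inf
  m_df <- q * (q + 1) / 2 - 1
  w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * k + 2) /
    (288 * (ndf * q * f)^2)
  pr1 <- stats::pchisq(chi, m_df, lower.tail = FALSE)
  pr2 <- stats::pchisq(chi, m_df + 4, lower.tail = FALSE)
  m_p <- pr1 + w2 * (pr2 - pr1)

  eps_gg <- sum(lam)^2 / (q * sum(lam^2))
  eps_hf <- (n * q * eps_gg - 2) / (q * (n - 1 - q * eps_gg))
  eps_hf <- min(1, eps_hf)

  p_unc <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  violated <- is.finite(m_p) && m_p < mauchly_alpha
  dfc <- if (violated) c(df1 * eps_hf, df2 * eps_hf) else c(df1, df2)
  p <- stats::pf(Fval, dfc[1], dfc[2], lower.tail = FALSE)
  list(F = Fval, df = c(df1, df2), df_corrected = dfc,
       p_uncorrected = p_unc, p = p, epsilon_hf = eps_hf,
       epsilon_gg = eps_gg, mauchly_w = W, mauchly_p = m_p,
       sphericity_violated = violated, n = n, k = k)
}

#' Bonferroni-corrected paired post hoc tests
#'
#' Dependent t-tests for the requested condition pairs with the
#' Bonferroni-adjusted significance threshold `family_alpha / m`
#' reported alongside the raw p-values (0.05 / 3 = 0.017 at 3 dp for
#' the three standard comparisons).
#'
#' @param means subjects x conditions matrix (named columns).
#' @param comparisons list of length-2 character vectors; default the
#'   three pairs of interest.
#' @param family_alpha family-wise alpha.
#' @return data.frame: comparison, t, df, p, bonferroni_threshold,
#'   significant.
#' @export
paired_posthocs <- function(means,
                            comparisons = list(c("positive", "now"),
                                               c("negative", "now"),
                                               c("positive", "negative")),
                            family_alpha = 0.05) {
  means <- as.matrix(means)
  m <- length(comparisons)
  thr <- family_alpha / m
  rows <- lapply(comparisons, function(cp) {
    if (!all(cp %in% colnames(means)))
      stop("paired_posthocs: unknown condition in comparison: ",
           paste(cp, collapse = " vs "))
    d <- means[, cp[1L]] - means[, cp[2L]]
    n <- length(d)
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(-abs(tt), n - 1)
    data.frame(comparison = paste(cp, collapse = " vs "), t = tt,
               df = n - 1L, p = p, bonferroni_threshold = thr,
               significant = p < thr)
  })
  do.call(rbind, rows)
}

#' Baseline assignment check
#'
#' Repeated-measures ANOVA on per-subject mean pre-experimental craving
#' of the snacks assigned to each strategy: with a successful random
#' assignment there is nothing to find (the study reported F(2,60) =
#' 1.434, p = 0.246 at n = 31). Degrees of freedom are the uncorrected
#' (2, 2(n-1)) pair.
#'
#' @param pre_ratings data.frame with columns `subject`, `condition`
#'   (assigned strategy) and `rating` (pre-experiment craving per
#'   snack).
#' @return the [rm_anova] result on the subject x strategy means.
#' @export
baseline_check <- function(pre_ratings) {
  req <- c("subject", "condition", "rating")
  if (!all(req %in% names(pre_ratings)))
    stop("baseline_check: need columns subject, condition, rating")
  agg <- stats::aggregate(rating ~ subject + condition, pre_ratings, mean)
  y <- stats::reshape(agg, idvar = "subject", timevar = "condition",
                      direction = "wide")
  y <- as.matrix(y[, -1L, drop = FALSE])
  colnames(y) <- sub("^rating\\.", "", colnames(y))
  rm_anova(y)
}

#' Simulate pre-experimental baseline ratings
#'
#' One craving rating per snack and subject, drawn with a common mean
#' regardless of the strategy the snack was later assigned to (the
#' null the baseline check should not reject).
#'
#' @param designs subject designs from [generate_design].
#' @param mean latent mean rating.
#' @param sd latent rating SD.
#' @param seed integer seed.
#' @return data.frame: subject, stimulus_id, condition, rating.
#' @export
simulate_baseline_ratings <- function(designs, mean = 3, sd = 1,
                                      seed = 1L) {
  old <- .set_seed(seed); on.exit(.restore_seed(old))
  do.call(rbind, lapply(designs, function(d) {
    sm <- d$stim_map
    raw <- round(stats::rnorm(nrow(sm), mean, sd))
    data.frame(subject = d$subject_id, stimulus_id = sm$stimulus_id,
               condition = sm$condition,
               rating = as.integer(pmin(5, pmax(1, raw))))
  }))
}
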