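#' Generate experimental designs
#'
#' Builds one design per subject for the craving-regulation task: five
#' runs of 36 trials (12 per condition), each trial a 2 s strategy cue
#' followed by a snack image of 6 +/- 1 s, a rating period, and an
#' inter-trial interval of 10 +/- 4 s. Each condition uses two visual
#' cues, balanced within run. Each of the 3 x 12 snack stimuli is bound
#' to exactly one condition within a subject; the snack-to-condition
#' assignment is rotated cyclically across subjects so no stimulus set
#' is tied to one strategy in the group.
#'
#' Jitters are discrete uniform (image on \{5, 6, 7\} s, ITI on
#' \{6, ..., 14\} s) drawn as shuffled balanced multisets per run, so
#' the per-run totals are fixed and the schedule always fits the run
#' (380 volumes x TR 2 s = 760 s with the defaults; free jitter draws
#' would overflow the run about half the time). Trial order is a
#' constrained shuffle with at most 3 consecutive same-condition trials.
#'
#' @param config a [pipeline_config].
#' @param seed integer seed; the whole design set is a deterministic
#'   function of it.
#' @param lead_in_s fixation time before the first trial (seconds).
#' @return list of per-subject designs, each a list with `subject_id`,
#'   `stim_map` (stimulus -> condition) and `events` (an event table as
#'   in [events], with `duration` the modeled cue+image epoch).
#' @export
generate_design <- function(config, seed = config$seed, lead_in_s = 4) {
  tpr <- config$trials_per_run
  if (tpr %% 3L != 0L)
    stop("generate_design: trials_per_run must be divisible by 3")
  per_cond <- tpr %/% 3L
  if (per_cond %% 2L != 0L)
    stop("generate_design: per-condition trial count must be even ",
         "(two cues per condition, balanced)")
  run_len <- config$n_volumes * config$tr_s
  n_stim <- 3L * per_cond

  old <- .set_seed(seed)
  on.exit(.restore_seed(old))

  lapply(seq_len(config$n_subjects), function(s) {
    # cyclic rotation of condition blocks over subjects
    rot <- .conditions[((seq_len(3L) - 1L + (s - 1L)) %% 3L) + 1L]
    stim_map <- data.frame(
      stimulus_id = seq_len(n_stim),
      condition = rep(rot, each = per_cond),
      stringsAsFactors = FALSE)

    runs <- lapply(seq_len(config$n_runs), function(r) {
      cond_seq <- .constrained_shuffle(rep(.conditions, each = per_cond),
                                       max_consec = 3L)
      img_dur <- sample(rep_len(c(5, 6, 7), tpr))
      iti <- sample(rep_len(6:14, tpr))
      # balanced cues and a one-pass shuffle of stimuli within condition
      cue <- integer(tpr)
      stim <- integer(tpr)
      for (cn in .conditions) {
        idx <- which(cond_seq == cn)
        cue[idx] <- sample(rep(c(1L, 2L), length(idx) %/% 2L))
        stim[idx] <- sample(stim_map$stimulus_id[stim_map$condition == cn])
      }
      onset <- numeric(tpr)
      t0 <- lead_in_s
      for (i in seq_len(tpr)) {
        onset[i] <- t0
        t0 <- t0 + 2 + img_dur[i] + 3 + iti[i]  # cue + image + rating + ITI
      }
      if (t0 > run_len + 1e-9)
        stop("generate_design: schedule (", t0, " s) overflows run length (",
             run_len, " s)")
      data.frame(onset = onset, duration = 2 + img_dur, condition = cond_seq,
                 cue_id = cue, stimulus_id = stim, run = r,
                 rating = NA_integer_, stringsAsFactors = FALSE)
    })
    list(subject_id = s, stim_map = stim_map,
         events = do.call(rbind, runs))
  })
}

# Shuffle with at most max_consec equal consecutive labels (rejection).
.constrained_shuffle <- function(x, max_consec = 3L, max_tries = 2000L) {
  for (i in seq_len(max_tries)) {
    y <- sample(x)
    r <- rle(y)
    if (max(r$lengths) <= max_consec) return(y)
  }
  stop("constrained shuffle failed after ", max_tries, " tries")
}

#' Simulate craving ratings
#'
#' One 5-point Likert rating per trial: a Gaussian draw around the
#' trial's condition mean, rounded and clipped to 1..5. With `sd = 0`
#' every rating equals the rounded condition mean.
#'
#' @param design one subject design from [generate_design], or a list of
#'   them (ratings are filled for each).
#' @param condition_means named numeric (positive, negative, now) in
#'   \[1, 5\].
#' @param sd rating noise standard deviation (on the latent scale).
#' @param seed integer seed.
#' @return the design(s) with the `rating` column filled.
#' @export
simulate_ratings <- function(design, condition_means, sd = 1, seed = 1L) {
  if (any(condition_means < 1 | condition_means > 5))
    stop("simulate_ratings: condition means must lie within [1, 5]")
  if (is.null(names(condition_means)) ||
      !all(.conditions %in% names(condition_means)))
    stop("simulate_ratings: condition_means must be named positive/negative/now")
  old <- .set_seed(seed)
  on.exit(.restore_seed(old))
  fill <- function(d) {
    mu <- condition_means[d$events$condition]
    raw <- mu + stats::rnorm(nrow(d$events), 0, sd)
    d$events$rating <- as.integer(pmin(5, pmax(1, round(raw))))
    d
  }
  if (!is.null(design$events)) fill(design) else lapply(design, fill)
}

# Seed plumbing: every exported stochastic operation takes an explicit
# seed, scopes it, and restores the caller's RNG state afterwards.
.set_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(old)
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# Derive a stream-specific child seed from a master seed.
.child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483587
}
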