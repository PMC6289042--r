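#' @name events
#' @title Event and rating tables
#'
#' @description
#' Trial events follow a BIDS-events-style dialect: a tab-separated file
#' with a header row and columns `onset`, `duration`, `condition`,
#' `cue_id`, `stimulus_id`, `run`, `rating`. `onset`/`duration` are in
#' seconds; `condition` is one of `positive`, `negative`, `now`;
#' `cue_id` is 1 or 2 (the two abstract visual cues per strategy);
#' `rating` is the 5-point craving rating (1-5) or `NA` if the trial's
#' rating window elapsed without a response.
NULL

.conditions <- c("positive", "negative", "now")

.validate_events <- function(ev) {
  req <- c("onset", "duration", "condition", "cue_id", "stimulus_id",
           "run", "rating")
  miss <- setdiff(req, names(ev))
  if (length(miss))
    stop("event table: missing columns: ", paste(miss, collapse = ", "))
  if (nrow(ev) == 0L) return(ev[req])
  bad <- setdiff(unique(ev$condition), .conditions)
  if (length(bad))
    stop("event table: unknown condition label(s): ",
         paste(bad, collapse = ", "),
         " (allowed: ", paste(.conditions, collapse = ", "), ")")
  if (any(!is.finite(ev$onset)) || any(!is.finite(ev$duration)))
    stop("event table: onset/duration must be numeric and finite")
  if (any(ev$duration <= 0)) stop("event table: durations must be > 0")
  for (r in unique(ev$run)) {
    on <- ev$onset[ev$run == r]
    if (any(diff(on) <= 0))
      stop("event table: onsets not strictly increasing within run ", r)
  }
  if (any(!ev$cue_id %in% c(1L, 2L)))
    stop("event table: cue_id must be 1 or 2")
  ev[req]
}

#' Read / write a trial event table
#'
#' @param path a TSV file in the events dialect described in [events].
#' @return `read_events`: a validated `data.frame` of events.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("read_events: no such file: ", path)
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", "n/a", ""))
  if (nrow(ev) == 0L) {
    ev <- data.frame(onset = numeric(0), duration = numeric(0),
                     condition = character(0), cue_id = integer(0),
                     stimulus_id = integer(0), run = integer(0),
                     rating = integer(0))
  }
  .validate_events(ev)
}

#' @rdname read_events
#' @param events a `data.frame` of events.
#' @export
write_events <- function(events, path) {
  events <- .validate_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read / write a table of numbers (TSV helpers)
#'
#' Plain TSV round-trip used for motion parameters, ratings summaries,
#' connectivity matrices and report tables.
#'
#' @param path file path.
#' @return `read_tsv`: a `data.frame`.
#' @keywords internal
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", "n/a", ""))
}

#' @rdname read_tsv
#' @param x a `data.frame`.
#' @keywords internal
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}
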