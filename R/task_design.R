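# RSVP task design: character pools, trial and session generation, scoring,
# and schedule/outcome serialization.

#' Character pools for RSVP streams
#'
#' Targets are drawn from the Latin alphabet excluding the nine letters that
#' are easily confused with digits or with each other (I, O, Q, S, U, V, W,
#' X, Z); distractors are the six digits 3, 4, 6, 7, 8, 9 chosen for the
#' same reason.
#'
#' @return A list with components `letters` (17 target letters) and
#'   `digits` (6 distractor digits), both character vectors.
#' @examples
#' pools <- rsvp_char_pools()
#' length(pools$letters) # 17
#' @export
rsvp_char_pools <- function() {
  excluded <- c("I", "O", "Q", "S", "U", "V", "W", "X", "Z")
  list(
    letters = setdiff(LETTERS, excluded),
    digits  = c("3", "4", "6", "7", "8", "9")
  )
}

#' Separations used by the RSVP task
#'
#' The separation of a trial is the number of digit distractors strictly
#' between the two letter targets; 0 means the targets are adjacent.
#'
#' @return Integer vector `c(0, 1, 2, 4, 5, 6, 8)`.
#' @export
rsvp_separations <- function() RSVP_SEPARATIONS

# Sample `n` digits with no two consecutive identical characters, continuing
# from `prev` (the last character already emitted, or NA at the stream start).
sample_distractors <- function(n, pool, prev = NA_character_) {
  out <- character(n)
  for (i in seq_len(n)) {
    choices <- if (is.na(prev)) pool else setdiff(pool, prev)
    out[i] <- sample(choices, 1L)
    prev <- out[i]
  }
  out
}

#' Generate one RSVP trial specification
#'
#' Builds the character stream for one trial: `pre_t1` leading digit
#' distractors, the first letter target T1, `separation` digits, the second
#' letter target T2, and `post_t2` trailing digits (so T2 is never the final
#' character and can itself be masked). No two consecutive distractors are
#' identical, and the two targets are distinct letters. Timing constants are
#' stored as metadata only; no stimulus presentation is performed.
#'
#' Uses R's global random number generator; call [set.seed()] first for a
#' reproducible trial.
#'
#' @param separation Number of intervening distractors, one of
#'   `rsvp_separations()`.
#' @param pre_t1 Number of distractors before T1. Default: drawn uniformly
#'   from 5..10.
#' @param post_t2 Number of distractors after T2 (default 3, must be >= 1).
#' @param trial_id Integer identifier stored in the spec.
#' @param char_duration_ms,frames_per_char Presentation metadata (defaults
#'   150 ms, 9 frames at 60 Hz).
#' @return An object of class `rsvp_trial`: a list with `trial_id`,
#'   `separation`, `stream` (character vector), `t1_pos`, `t2_pos` (1-based
#'   indices), `t1`, `t2`, `char_duration_ms`, `frames_per_char`.
#' @examples
#' set.seed(1)
#' tr <- generate_trial(2)
#' tr$t2_pos - tr$t1_pos # separation + 1 = 3
#' @export
generate_trial <- function(separation, pre_t1 = NULL, post_t2 = 3L,
                           trial_id = 0L,
                           char_duration_ms = 150, frames_per_char = 9L) {
  separation <- assert_separation(separation)
  if (is.null(pre_t1)) pre_t1 <- sample(5:10, 1L)
  pre_t1 <- as.integer(pre_t1)
  post_t2 <- as.integer(post_t2)
  if (pre_t1 < 1L || post_t2 < 1L) {
    stop_rsvp("stream too short: pre_t1 and post_t2 must each be >= 1",
              "stream_too_short")
  }
  pools <- rsvp_char_pools()
  targets <- sample(pools$letters, 2L)

  pre <- sample_distractors(pre_t1, pools$digits)
  mid <- sample_distractors(separation, pools$digits,
                            prev = pre[length(pre)])
  prev_for_post <- if (separation > 0L) mid[length(mid)] else pre[length(pre)]
  post <- sample_distractors(post_t2, pools$digits, prev = prev_for_post)

  stream <- c(pre, targets[1L], mid, targets[2L], post)
  t1_pos <- pre_t1 + 1L
  t2_pos <- t1_pos + separation + 1L
  structure(
    list(
      trial_id = as.integer(trial_id),
      separation = separation,
      stream = stream,
      t1_pos = t1_pos,
      t2_pos = t2_pos,
      t1 = targets[1L],
      t2 = targets[2L],
      char_duration_ms = char_duration_ms,
      frames_per_char = as.integer(frames_per_char)
    ),
    class = "rsvp_trial"
  )
}

#' @export
print.rsvp_trial <- function(x, ...) {
  cat(sprintf("RSVP trial %d (separation %d): %s\n", x$trial_id, x$separation,
              paste(x$stream, collapse = "")))
  cat(sprintf("  T1 = %s at %d, T2 = %s at %d\n", x$t1, x$t1_pos, x$t2, x$t2_pos))
  invisible(x)
}

#' Generate a full RSVP session schedule
#'
#' A session consists of 70 trials, 10 at each of the seven separations,
#' presented in random order.
#'
#' @param seed Optional integer seed; if supplied the schedule is
#'   reproducible, otherwise the current RNG state is used.
#' @param trials_per_separation Trials at each separation (default 10).
#' @param ... Passed to [generate_trial()] (e.g. `post_t2`).
#' @return A list of `rsvp_trial` objects with `trial_id` 1..n in
#'   presentation order.
#' @examples
#' sess <- generate_session(seed = 1)
#' length(sess) # 70
#' @export
generate_session <- function(seed = NULL, trials_per_separation = 10L, ...) {
  if (!is.null(seed)) set.seed(seed)
  seps <- sample(rep(RSVP_SEPARATIONS, each = trials_per_separation))
  lapply(seq_along(seps), function(i) {
    generate_trial(seps[i], trial_id = i, ...)
  })
}

#' Score reported targets against a trial specification
#'
#' Matching is case-insensitive (targets are reported verbally and entered
#' by a technician, so letter case carries no information); a missing report
#' (`NULL` or `NA`) is incorrect.
#'
#' @param spec An `rsvp_trial`.
#' @param reported_t1,reported_t2 Single characters or `NULL`/`NA`.
#' @return An object of class `rsvp_outcome`: list with `trial_id`,
#'   `separation`, `t1_correct`, `t2_correct`.
#' @examples
#' set.seed(1)
#' tr <- generate_trial(0)
#' score_trial(tr, tolower(tr$t1), "?")$t1_correct # TRUE
#' @export
score_trial <- function(spec, reported_t1, reported_t2) {
  stopifnot(inherits(spec, "rsvp_trial"))
  match_report <- function(target, reported) {
    if (is.null(reported) || length(reported) == 0L || is.na(reported)) {
      return(FALSE)
    }
    toupper(as.character(reported)) == toupper(target)
  }
  structure(
    list(
      trial_id = spec$trial_id,
      separation = spec$separation,
      t1_correct = match_report(spec$t1, reported_t1),
      t2_correct = match_report(spec$t2, reported_t2)
    ),
    class = "rsvp_outcome"
  )
}

#' Convert scored outcomes to a data frame
#'
#' @param outcomes A list of `rsvp_outcome` objects.
#' @param participant_id Identifier attached to every row.
#' @return Data frame with columns `participant_id`, `trial_id`,
#'   `separation`, `t1_correct`, `t2_correct`.
#' @export
outcomes_df <- function(outcomes, participant_id = "P1") {
  data.frame(
    participant_id = participant_id,
    trial_id = vapply(outcomes, `[[`, integer(1), "trial_id"),
    separation = vapply(outcomes, `[[`, integer(1), "separation"),
    t1_correct = vapply(outcomes, `[[`, logical(1), "t1_correct"),
    t2_correct = vapply(outcomes, `[[`, logical(1), "t2_correct"),
    stringsAsFactors = FALSE
  )
}

#' Serialize a session schedule to JSON
#'
#' One object per trial: `trial_id`, `separation`, `stream` (a single
#' string), `t1_pos`, `t2_pos` (1-based), `t1`, `t2`, timing metadata.
#' [read_session_json()] restores an identical schedule.
#'
#' @param session List of `rsvp_trial` objects.
#' @param path File path to write.
#' @export
write_session_json <- function(session, path) {
  rows <- lapply(session, function(tr) {
    list(
      trial_id = tr$trial_id,
      separation = tr$separation,
      stream = paste(tr$stream, collapse = ""),
      t1_pos = tr$t1_pos,
      t2_pos = tr$t2_pos,
      t1 = tr$t1,
      t2 = tr$t2,
      char_duration_ms = tr$char_duration_ms,
      frames_per_char = tr$frames_per_char
    )
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_session_json
#' @return `read_session_json()` returns the list of `rsvp_trial` objects.
#' @export
read_session_json <- function(path) {
  rows <- jsonlite::read_json(path)
  lapply(rows, function(r) {
    structure(
      list(
        trial_id = as.integer(r$trial_id),
        separation = as.integer(r$separation),
        stream = strsplit(r$stream, "")[[1L]],
        t1_pos = as.integer(r$t1_pos),
        t2_pos = as.integer(r$t2_pos),
        t1 = r$t1,
        t2 = r$t2,
        char_duration_ms = as.numeric(r$char_duration_ms),
        frames_per_char = as.integer(r$frames_per_char)
      ),
      class = "rsvp_trial"
    )
  })
}

#' Read and write trial-outcome tables
#'
#' Plain CSV with header
#' `participant_id,trial_id,separation,t1_correct,t2_correct`.
#'
#' @param outcomes Data frame as produced by [outcomes_df()] or
#'   [simulate_cohort()].
#' @param path File path.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  req <- c("participant_id", "trial_id", "separation", "t1_correct", "t2_correct")
  missing_cols <- setdiff(req, names(outcomes))
  if (length(missing_cols) > 0L) {
    stop_rsvp(paste("missing columns:", paste(missing_cols, collapse = ", ")),
              "missing_columns")
  }
  utils::write.csv(outcomes[req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes_csv
#' @export
read_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$t1_correct <- as.logical(df$t1_correct)
  df$t2_correct <- as.logical(df$t2_correct)
  df
}
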