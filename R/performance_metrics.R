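# Attentional blink / attentional masking performance curves, global summary
# metrics and the classification feature matrix.

#' Per-separation AB/AM performance curve
#'
#' For each separation the attentional blink is the conditional frequency
#' AB(s) = P(T2 correct | T1 correct) = n_both / n_t1, and the attentional
#' masking is AM(s) = P(T1 correct | T2 correct) = n_both / n_t2. A
#' separation with a zero denominator yields `NA` (the conditional is
#' undefined), never 0.
#'
#' @param outcomes Data frame with columns `separation`, `t1_correct`,
#'   `t2_correct` (one row per trial), e.g. from [outcomes_df()] or a
#'   cohort's `outcomes` table filtered to one participant.
#' @return An object of class `rsvp_curve`: a data frame with one row per
#'   separation present and columns `separation`, `n_trials`, `n_t1`,
#'   `n_t2`, `n_both`, `ab`, `am`.
#' @examples
#' oc <- data.frame(separation = 0, t1_correct = c(TRUE, TRUE, FALSE),
#'                  t2_correct = c(TRUE, FALSE, TRUE))
#' compute_curve(oc)$ab # 0.5
#' @export
compute_curve <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0L) {
    stop_rsvp("outcomes must contain at least one trial", "empty_outcomes")
  }
  seps <- sort(unique(outcomes$separation))
  rows <- lapply(seps, function(s) {
    oc <- outcomes[outcomes$separation == s, , drop = FALSE]
    n_t1 <- sum(oc$t1_correct)
    n_t2 <- sum(oc$t2_correct)
    n_both <- sum(oc$t1_correct & oc$t2_correct)
    data.frame(
      separation = as.integer(s),
      n_trials = nrow(oc),
      n_t1 = n_t1,
      n_t2 = n_t2,
      n_both = n_both,
      ab = if (n_t1 > 0L) n_both / n_t1 else NA_real_,
      am = if (n_t2 > 0L) n_both / n_t2 else NA_real_
    )
  })
  curve <- do.call(rbind, rows)
  class(curve) <- c("rsvp_curve", "data.frame")
  curve
}

#' Global AB and AM summary metrics
#'
#' The global metrics are the mean of the per-separation AB (respectively
#' AM) over separations 0, 1 and 2 — the region where group differences are
#' most pronounced — expressed on a 0-100 percentage scale.
#'
#' @param curve An `rsvp_curve` from [compute_curve()].
#' @return List with `global_ab` and `global_am`, both in `[0, 100]`.
#' @examples
#' oc <- expand.grid(separation = c(0, 1, 2), trial = 1:10)
#' oc$t1_correct <- TRUE; oc$t2_correct <- TRUE
#' compute_global(compute_curve(oc))$global_ab # 100
#' @export
compute_global <- function(curve) {
  stopifnot(inherits(curve, "rsvp_curve"))
  idx <- match(GLOBAL_SEPARATIONS, curve$separation)
  if (anyNA(idx)) {
    stop_rsvp(sprintf("curve lacks separation(s) %s",
                      paste(GLOBAL_SEPARATIONS[is.na(idx)], collapse = ", ")),
              "undefined_global")
  }
  ab <- curve$ab[idx]
  am <- curve$am[idx]
  if (anyNA(ab) || anyNA(am)) {
    bad <- GLOBAL_SEPARATIONS[is.na(ab) | is.na(am)]
    stop_rsvp(sprintf("AB/AM undefined at separation(s) %s",
                      paste(bad, collapse = ", ")),
              "undefined_global")
  }
  list(global_ab = 100 * mean(ab), global_am = 100 * mean(am))
}

# Length-14 feature vector: ab(s) for s in ascending separation order,
# then am(s). NA cells (zero-denominator conditionals) are imputed as 0 —
# the conservative worst-performance score — with a warning.
feature_vector <- function(curve, impute = TRUE) {
  idx <- match(RSVP_SEPARATIONS, curve$separation)
  if (anyNA(idx)) {
    stop_rsvp(sprintf("curve lacks separation(s) %s",
                      paste(RSVP_SEPARATIONS[is.na(idx)], collapse = ", ")),
              "undefined_feature")
  }
  v <- c(curve$ab[idx], curve$am[idx])
  names(v) <- c(paste0("ab_", RSVP_SEPARATIONS), paste0("am_", RSVP_SEPARATIONS))
  if (anyNA(v)) {
    if (!impute) {
      stop_rsvp(sprintf("undefined feature(s): %s",
                        paste(names(v)[is.na(v)], collapse = ", ")),
                "undefined_feature")
    }
    warning(sprintf("imputing 0 for undefined feature(s): %s",
                    paste(names(v)[is.na(v)], collapse = ", ")))
    v[is.na(v)] <- 0
  }
  v
}

#' Build the classification feature matrix
#'
#' One row per participant, 14 columns: per-separation AB values (ascending
#' separation), then per-separation AM values. Column names (`ab_0` ...
#' `am_8`) fix the ordering and are written into CSV headers. Undefined
#' conditionals (zero denominators) are imputed as 0, the conservative
#' worst-performance score, with a warning naming participant and cell.
#'
#' @param cohort An `rsvp_cohort` (see [simulate_cohort()]), or any list
#'   with `participants` and `outcomes` data frames in the cohort layout.
#' @return List with `features` (numeric matrix n x 14, rownames =
#'   participant ids) and `labels` (character vector of `"CI"`/`"HC"`).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_ci = 2, n_hc = 2, seed = 1))
#' dim(build_feature_matrix(coh)$features) # 4 x 14
#' @export
build_feature_matrix <- function(cohort) {
  parts <- cohort$participants
  rows <- lapply(seq_len(nrow(parts)), function(i) {
    pid <- parts$participant_id[i]
    oc <- cohort$outcomes[cohort$outcomes$participant_id == pid, , drop = FALSE]
    withCallingHandlers(
      feature_vector(compute_curve(oc)),
      warning = function(w) {
        warning(sprintf("participant %s: %s", pid, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  })
  features <- do.call(rbind, rows)
  rownames(features) <- parts$participant_id
  list(features = features, labels = as.character(parts$group))
}

#' Per-participant curves and global metrics for a cohort
#'
#' `participant_curves()` returns the per-separation performance table for
#' every participant; `participant_globals()` the global AB/AM summary per
#' participant. With `impute = TRUE` (default) undefined conditionals at
#' separations 0-2 are scored 0 with a warning, so the result is defined
#' for every participant; with `impute = FALSE` such participants raise the
#' error from [compute_global()].
#'
#' @param cohort An `rsvp_cohort`.
#' @param impute Impute undefined conditionals as 0 before summarizing?
#' @return `participant_curves()`: data frame of stacked curves with a
#'   `participant_id` column. `participant_globals()`: data frame with
#'   `participant_id`, `group`, `cdt_score`, `phototest_score`,
#'   `global_ab`, `global_am`.
#' @export
participant_curves <- function(cohort) {
  parts <- cohort$participants
  do.call(rbind, lapply(seq_len(nrow(parts)), function(i) {
    pid <- parts$participant_id[i]
    oc <- cohort$outcomes[cohort$outcomes$participant_id == pid, , drop = FALSE]
    cv <- compute_curve(oc)
    cbind(participant_id = pid, as.data.frame(cv))
  }))
}

#' @rdname participant_curves
#' @export
participant_globals <- function(cohort, impute = TRUE) {
  parts <- cohort$participants
  glob <- lapply(seq_len(nrow(parts)), function(i) {
    pid <- parts$participant_id[i]
    oc <- cohort$outcomes[cohort$outcomes$participant_id == pid, , drop = FALSE]
    curve <- compute_curve(oc)
    if (impute) {
      idx <- match(GLOBAL_SEPARATIONS, curve$separation)
      bad <- idx[!is.na(idx)][is.na(curve$ab[idx]) | is.na(curve$am[idx])]
      if (length(bad) > 0L) {
        warning(sprintf(
          "participant %s: undefined conditional(s) at separation(s) %s scored 0",
          pid, paste(curve$separation[bad], collapse = ", ")))
        curve$ab[bad][is.na(curve$ab[bad])] <- 0
        curve$am[bad][is.na(curve$am[bad])] <- 0
      }
    }
    g <- compute_global(curve)
    data.frame(participant_id = pid, global_ab = g$global_ab,
               global_am = g$global_am)
  })
  merge(parts, do.call(rbind, glob), by = "participant_id", sort = FALSE)
}
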