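# Synthetic CI/HC cohort generator: joint (T1,T2) outcome model per group and
# separation, plus rounded truncated-normal CDT and Phototest scores.

#' Build a joint outcome model from target conditionals
#'
#' The generator is parameterized by the joint probabilities of the four
#' (T1 correct, T2 correct) outcomes, because the conditionals AB and AM
#' alone do not identify a sampling model. This helper inverts the
#' conditionals: given AB = p11/(p11+p10), AM = p11/(p11+p01) and a chosen
#' p11 it returns (p11, p10, p01, p00).
#'
#' @param ab,am Target conditional probabilities in (0, 1].
#' @param p11 Joint probability that both targets are reported correctly;
#'   must satisfy `p11 * (1/ab + 1/am - 1) <= 1` so that p00 >= 0.
#' @return Named numeric vector `c(p11, p10, p01, p00)` summing to 1.
#' @export
joint_from_conditionals <- function(ab, am, p11) {
  stopifnot(ab > 0, ab <= 1, am > 0, am <= 1, p11 >= 0)
  p10 <- p11 * (1 / ab - 1)
  p01 <- p11 * (1 / am - 1)
  p00 <- 1 - p11 - p10 - p01
  if (p00 < -1e-12) {
    stop_rsvp(sprintf("p11 = %.3f too large for ab = %.3f, am = %.3f", p11, ab, am),
              "invalid_model")
  }
  c(p11 = p11, p10 = p10, p01 = p01, p00 = max(p00, 0))
}

#' Default synthetic outcome model
#'
#' Joint (T1, T2) outcome probabilities per group and separation, chosen so
#' that the analytic conditionals at separations 0-2 are flat and their
#' mean (x100) equals the published group means of the global metrics
#' (CI: AB 55.88, AM 47.32; HC: AB 88.61, AM 69.89). At separations 4-8 the
#' conditionals rise toward recovery for the CI group and stay high for the
#' HC group — a qualitative recovery shape only. The joint probability p11
#' is a free parameter not identified by group summaries; defaults are 0.30
#' (CI) and 0.60 (HC) at separations 0-2, rising at larger separations.
#'
#' Score distributions are rounded, support-truncated normals with the
#' published group means and sd = SEM * sqrt(n): CDT (support 0-7) CI
#' 5.69 (sd 1.77), HC 6.56 (sd 0.96); Phototest (support >= 0) CI 33.08
#' (sd 5.88), HC 41.56 (sd 3.21).
#'
#' @return An object of class `rsvp_outcome_model`: list with `joint` (data
#'   frame: `group`, `separation`, `p11`, `p10`, `p01`, `p00`) and `scores`
#'   (nested list: test -> group -> `mean`, `sd`, `min`, `max`).
#' @examples
#' m <- default_outcome_model()
#' model_global(m, "HC")$global_am # 69.89
#' @export
default_outcome_model <- function() {
  ci_ab <- c(rep(0.5588, 3), 0.65, 0.72, 0.78, 0.85)
  ci_am <- c(rep(0.4732, 3), 0.60, 0.68, 0.75, 0.82)
  ci_p11 <- c(rep(0.30, 3), 0.40, 0.45, 0.50, 0.55)
  hc_ab <- c(rep(0.8861, 3), 0.92, 0.93, 0.94, 0.95)
  hc_am <- c(rep(0.6989, 3), 0.80, 0.84, 0.87, 0.90)
  hc_p11 <- c(rep(0.60, 3), 0.68, 0.70, 0.72, 0.75)
  rows <- list()
  for (i in seq_along(RSVP_SEPARATIONS)) {
    rows[[length(rows) + 1L]] <- c(group = "CI", separation = RSVP_SEPARATIONS[i],
                                   joint_from_conditionals(ci_ab[i], ci_am[i], ci_p11[i]))
    rows[[length(rows) + 1L]] <- c(group = "HC", separation = RSVP_SEPARATIONS[i],
                                   joint_from_conditionals(hc_ab[i], hc_am[i], hc_p11[i]))
  }
  joint <- do.call(rbind.data.frame, lapply(rows, function(r) {
    data.frame(group = r[["group"]], separation = as.integer(r[["separation"]]),
               p11 = as.numeric(r[["p11"]]), p10 = as.numeric(r[["p10"]]),
               p01 = as.numeric(r[["p01"]]), p00 = as.numeric(r[["p00"]]),
               stringsAsFactors = FALSE)
  }))
  scores <- list(
    cdt = list(
      CI = list(mean = 5.69, sd = 0.49 * sqrt(13), min = 0, max = 7),
      HC = list(mean = 6.56, sd = 0.32 * sqrt(9), min = 0, max = 7)
    ),
    phototest = list(
      CI = list(mean = 33.08, sd = 1.63 * sqrt(13), min = 0, max = Inf),
      HC = list(mean = 41.56, sd = 1.07 * sqrt(9), min = 0, max = Inf)
    )
  )
  validate_outcome_model(structure(list(joint = joint, scores = scores),
                                   class = "rsvp_outcome_model"))
}

validate_outcome_model <- function(model) {
  j <- model$joint
  sums <- j$p11 + j$p10 + j$p01 + j$p00
  if (any(abs(sums - 1) > 1e-9) ||
      any(j$p11 < 0 | j$p10 < 0 | j$p01 < 0 | j$p00 < 0)) {
    stop_rsvp("joint outcome probabilities must be >= 0 and sum to 1",
              "invalid_model")
  }
  if (!all(GROUP_LEVELS %in% j$group)) {
    stop_rsvp("model must cover both groups", "invalid_model")
  }
  model
}

#' Analytic conditionals and global metrics of an outcome model
#'
#' `model_conditionals()` returns the model-implied AB = p11/(p11+p10) and
#' AM = p11/(p11+p01) per group and separation; `model_global()` averages
#' them over separations 0-2 for one group (x100), i.e. the population
#' value of the global metrics under the model.
#'
#' @param model An `rsvp_outcome_model`.
#' @param group `"CI"` or `"HC"` (for `model_global()`).
#' @return `model_conditionals()`: data frame `group`, `separation`, `ab`,
#'   `am`. `model_global()`: list with `global_ab`, `global_am`.
#' @export
model_conditionals <- function(model) {
  j <- model$joint
  data.frame(group = j$group, separation = j$separation,
             ab = j$p11 / (j$p11 + j$p10),
             am = j$p11 / (j$p11 + j$p01),
             stringsAsFactors = FALSE)
}

#' @rdname model_conditionals
#' @export
model_global <- function(model, group) {
  group <- assert_group(group)
  cond <- model_conditionals(model)
  cond <- cond[cond$group == group & cond$separation %in% GLOBAL_SEPARATIONS, ]
  list(global_ab = 100 * mean(cond$ab), global_am = 100 * mean(cond$am))
}

#' Cohort configuration
#'
#' @param n_ci,n_hc Group sizes (defaults 13 cognitively impaired, 9
#'   healthy controls; both must be >= 1).
#' @param trials_per_separation RSVP trials at each of the 7 separations
#'   (default 10, i.e. 70 trials per participant).
#' @param model An `rsvp_outcome_model` (default [default_outcome_model()]).
#' @param seed Optional integer seed for reproducible simulation.
#' @return An object of class `rsvp_cohort_config`.
#' @export
cohort_config <- function(n_ci = 13L, n_hc = 9L, trials_per_separation = 10L,
                          model = default_outcome_model(), seed = NULL) {
  if (n_ci < 1L || n_hc < 1L) {
    stop_rsvp("n_ci and n_hc must both be >= 1", "invalid_config")
  }
  validate_outcome_model(model)
  structure(
    list(n_ci = as.integer(n_ci), n_hc = as.integer(n_hc),
         trials_per_separation = as.integer(trials_per_separation),
         model = model, seed = seed),
    class = "rsvp_cohort_config"
  )
}

# Rounded truncated-normal integer score: draw, round, reject if outside
# the support.
draw_score <- function(spec) {
  repeat {
    x <- round(stats::rnorm(1L, spec$mean, spec$sd))
    if (x >= spec$min && x <= spec$max) return(as.integer(x))
  }
}

#' Simulate one participant
#'
#' Trial outcomes are drawn directly from the group's joint (T1, T2)
#' outcome probabilities at each separation (character streams are not
#' materialized; use [generate_session()] when the full task design is
#' needed). CDT and Phototest scores are drawn from the model's rounded
#' truncated-normal score distributions. Uses the global RNG; seed it (or
#' use the config seed via [simulate_cohort()]) for reproducibility.
#'
#' @param group `"CI"` or `"HC"`.
#' @param config An `rsvp_cohort_config`.
#' @param participant_id Identifier for the record.
#' @return List with `participant_id`, `group`, `cdt_score`,
#'   `phototest_score` and an `outcomes` data frame (one row per trial).
#' @export
simulate_participant <- function(group, config = cohort_config(),
                                 participant_id = "P1") {
  group <- assert_group(group)
  j <- config$model$joint
  n <- config$trials_per_separation
  seps <- rep(RSVP_SEPARATIONS, each = n)
  # outcome codes: 1 = (1,1), 2 = (1,0), 3 = (0,1), 4 = (0,0)
  draws <- unlist(lapply(RSVP_SEPARATIONS, function(s) {
    p <- j[j$group == group & j$separation == s, c("p11", "p10", "p01", "p00")]
    if (nrow(p) != 1L) {
      stop_rsvp(sprintf("model lacks probabilities for group %s, separation %d",
                        group, s), "invalid_model")
    }
    sample.int(4L, n, replace = TRUE, prob = as.numeric(p))
  }))
  outcomes <- data.frame(
    participant_id = participant_id,
    trial_id = seq_along(seps),
    separation = seps,
    t1_correct = draws %in% c(1L, 2L),
    t2_correct = draws %in% c(1L, 3L),
    stringsAsFactors = FALSE
  )
  # shuffle presentation order as in a real session
  outcomes <- outcomes[sample.int(nrow(outcomes)), ]
  outcomes$trial_id <- seq_len(nrow(outcomes))
  rownames(outcomes) <- NULL
  list(
    participant_id = participant_id,
    group = group,
    cdt_score = draw_score(config$model$scores$cdt[[group]]),
    phototest_score = draw_score(config$model$scores$phototest[[group]]),
    outcomes = outcomes
  )
}

#' Simulate a full cohort
#'
#' Generates `n_ci` cognitively-impaired and `n_hc` healthy-control
#' participants (defaults 13 and 9) from the configured outcome model.
#'
#' @param config An `rsvp_cohort_config`.
#' @return An object of class `rsvp_cohort`: list with `participants`
#'   (data frame `participant_id`, `group`, `cdt_score`,
#'   `phototest_score`), `outcomes` (stacked trial-outcome data frame) and
#'   `seed`.
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 8))
#' table(coh$participants$group) # 13 CI, 9 HC
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- c(sprintf("CI%02d", seq_len(config$n_ci)),
           sprintf("HC%02d", seq_len(config$n_hc)))
  groups <- c(rep("CI", config$n_ci), rep("HC", config$n_hc))
  recs <- lapply(seq_along(ids), function(i) {
    simulate_participant(groups[i], config, participant_id = ids[i])
  })
  participants <- data.frame(
    participant_id = ids,
    group = groups,
    cdt_score = vapply(recs, `[[`, integer(1), "cdt_score"),
    phototest_score = vapply(recs, `[[`, integer(1), "phototest_score"),
    stringsAsFactors = FALSE
  )
  outcomes <- do.call(rbind, lapply(recs, `[[`, "outcomes"))
  structure(list(participants = participants, outcomes = outcomes,
                 seed = config$seed),
            class = "rsvp_cohort")
}

#' @export
print.rsvp_cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("RSVP cohort: %d participants (%s), %d trial outcomes\n",
              nrow(x$participants),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$outcomes)))
  invisible(x)
}

#' Write or read a cohort as plain CSV files
#'
#' `participants.csv` holds `participant_id,group,cdt_score,phototest_score`
#' and `outcomes.csv` the trial outcomes; the round-trip is lossless.
#'
#' @param cohort An `rsvp_cohort`.
#' @param dir Directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  write_outcomes_csv(cohort$outcomes, file.path(dir, "outcomes.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  outcomes <- read_outcomes_csv(file.path(dir, "outcomes.csv"))
  structure(list(participants = participants, outcomes = outcomes, seed = NULL),
            class = "rsvp_cohort")
}

#' Write or read an outcome model as JSON
#'
#' @param model An `rsvp_outcome_model`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(joint = model$joint, scores = model$scores), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$joint$separation <- as.integer(raw$joint$separation)
  # numeric leaves may round-trip as strings (e.g. "Inf" for an unbounded
  # score support); coerce them back
  scores <- lapply(raw$scores, function(test) {
    lapply(test, function(grp) lapply(grp, as.numeric))
  })
  validate_outcome_model(structure(list(joint = raw$joint, scores = scores),
                                   class = "rsvp_outcome_model"))
}
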