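# Confusion matrices, macro precision/recall, accuracy with Wilson score
# intervals, and assembly of the full study report.

#' Confusion matrix with CI as the positive class
#'
#' @param true_labels,predicted_labels Equal-length `"CI"`/`"HC"` vectors.
#' @return An object of class `rsvp_confusion`: list with `tp` (CI
#'   predicted CI), `fn` (CI predicted HC), `fp` (HC predicted CI), `tn`
#'   (HC predicted HC).
#' @examples
#' confusion(c("CI", "CI", "HC"), c("CI", "HC", "HC"))
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_rsvp("label vectors must have equal length", "length_mismatch")
  }
  true_labels <- assert_labels(true_labels)
  predicted_labels <- assert_labels(predicted_labels)
  structure(
    list(
      tp = sum(true_labels == "CI" & predicted_labels == "CI"),
      fn = sum(true_labels == "CI" & predicted_labels == "HC"),
      fp = sum(true_labels == "HC" & predicted_labels == "CI"),
      tn = sum(true_labels == "HC" & predicted_labels == "HC")
    ),
    class = "rsvp_confusion"
  )
}

#' Build a confusion object from the four counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts (CI is the positive
#'   class; `fn` is CI predicted HC, `fp` is HC predicted CI).
#' @return An `rsvp_confusion`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_rsvp("confusion counts must be non-negative integers", "invalid_counts")
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn), class = "rsvp_confusion")
}

#' @export
print.rsvp_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(true = c("CI", "HC"), predicted = c("CI", "HC")))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Interval for the success probability of a series of Bernoulli trials,
#' obtained by inverting the normal score test:
#' `(p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)` with
#' `z` the standard-normal quantile at `(1 + confidence)/2`.
#'
#' @param successes,n Number of successes and trials,
#'   `0 <= successes <= n`, `n >= 1`.
#' @param confidence Confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' round(wilson_interval(20, 22), 2) # 0.72 0.97
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n < 1 || successes < 0 || successes > n ||
      confidence <= 0 || confidence >= 1) {
    stop_rsvp("require 0 <= successes <= n, n >= 1, confidence in (0,1)",
              "invalid_interval_input")
  }
  z <- stats::qnorm((1 + confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = centre - half, high = centre + half)
}

#' Classification report from a confusion matrix
#'
#' Macro-averaged precision and recall (the unweighted mean of the
#' per-class values, CI and HC weighted equally), accuracy, and the Wilson
#' score confidence interval for accuracy treating the predictions as a
#' series of Bernoulli trials. A per-class precision with an empty
#' denominator (no predictions for that class) contributes 0 with a
#' warning.
#'
#' @param cm An `rsvp_confusion`.
#' @param confidence Confidence level for the accuracy interval.
#' @param method Optional method name stored in the report.
#' @return An object of class `rsvp_report`: list with `precision_macro`,
#'   `recall_macro`, `accuracy`, `ci_low`, `ci_high`, `method`, `n`.
#' @examples
#' rep <- summarize_confusion(confusion_counts(12, 1, 1, 8))
#' round(rep$accuracy, 2) # 0.91
#' @export
summarize_confusion <- function(cm, confidence = 0.95, method = NA_character_) {
  stopifnot(inherits(cm, "rsvp_confusion"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0L) stop_rsvp("confusion matrix is empty", "empty_confusion")
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s has empty denominator; contributing 0", what))
      return(0)
    }
    num / den
  }
  prec_ci <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision for class CI")
  prec_hc <- safe_ratio(cm$tn, cm$tn + cm$fn, "precision for class HC")
  rec_ci <- safe_ratio(cm$tp, cm$tp + cm$fn, "recall for class CI")
  rec_hc <- safe_ratio(cm$tn, cm$tn + cm$fp, "recall for class HC")
  accuracy <- (cm$tp + cm$tn) / n
  ci <- wilson_interval(cm$tp + cm$tn, n, confidence)
  structure(
    list(
      precision_macro = (prec_ci + prec_hc) / 2,
      recall_macro = (rec_ci + rec_hc) / 2,
      accuracy = accuracy,
      ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
      method = method, n = n
    ),
    class = "rsvp_report"
  )
}

#' @export
print.rsvp_report <- function(x, ...) {
  cat(sprintf("%s: precision %.2f, recall %.2f, accuracy %.2f [%.2f, %.2f] (n = %d)\n",
              if (is.na(x$method)) "classifier" else x$method,
              x$precision_macro, x$recall_macro, x$accuracy,
              x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Run the full screening analysis on a cohort
#'
#' Assembles the complete study report: the group-comparison table (means
#' with SEM, U, exact p, effect size for CDT, Phototest and the two global
#' RSVP metrics), the five classification procedures (fixed CDT cutoff,
#' fixed Phototest cutoff, sequential CDT -> Phototest, LOOCV threshold on
#' global AM, grid-searched LOOCV logistic regression on the 22 x 14
#' feature matrix), their classification reports with Wilson intervals,
#' their confusion matrices, and the selected logistic hyperparameters.
#'
#' @param cohort An `rsvp_cohort`.
#' @param cdt_cutoff,phototest_cutoff Fixed literature cutoffs (6, 29).
#' @param penalties,c_values Logistic grid (defaults l1/l2 and
#'   10^-7 ... 10^7).
#' @param standardize Z-score logistic features per training fold?
#' @param confidence Confidence level for accuracy intervals.
#' @return An object of class `rsvp_study_report`: list with
#'   `group_stats`, `classification` (data frame, one row per method),
#'   `confusions` (named list of `rsvp_confusion`), `predictions` (data
#'   frame `participant_id`, `true_label`, `predicted_label`, `method`),
#'   `logistic_grid`, `best_logistic`, `seed`.
#' @examples
#' \donttest{
#' rep <- build_report(simulate_cohort(cohort_config(seed = 8)))
#' rep$classification
#' }
#' @export
build_report <- function(cohort, cdt_cutoff = 6, phototest_cutoff = 29,
                         penalties = c("l1", "l2"), c_values = 10^(-7:7),
                         standardize = TRUE, confidence = 0.95) {
  for (col in c("participant_id", "group", "cdt_score", "phototest_score")) {
    if (is.null(cohort$participants[[col]])) {
      stop_rsvp(paste("cohort participants table lacks column", col),
                "missing_columns")
    }
  }
  glob <- suppressWarnings(participant_globals(cohort, impute = TRUE))
  truth <- as.character(glob$group)
  stats_tab <- group_stats_table(cohort)

  fm <- suppressWarnings(build_feature_matrix(cohort))
  gs <- grid_search_loocv(fm$features, fm$labels, penalties = penalties,
                          c_values = c_values, standardize = standardize)
  am_loocv <- loocv_threshold(glob$global_am, truth)

  preds <- list(
    CDT = threshold_predict(glob$cdt_score, cdt_cutoff),
    Phototest = threshold_predict(glob$phototest_score, phototest_cutoff),
    Sequential = sequential_predict(glob$cdt_score, glob$phototest_score,
                                    cdt_cutoff, phototest_cutoff),
    `RSVP (AM)` = am_loocv$predictions,
    `RSVP (LR)` = gs$loocv$predictions
  )
  confusions <- lapply(preds, confusion, true_labels = truth)
  reports <- Map(function(cm, nm) summarize_confusion(cm, confidence, nm),
                 confusions, names(confusions))
  classification <- do.call(rbind, lapply(reports, function(r) {
    data.frame(method = r$method, precision = r$precision_macro,
               recall = r$recall_macro, accuracy = r$accuracy,
               ci_low = r$ci_low, ci_high = r$ci_high,
               stringsAsFactors = FALSE)
  }))
  rownames(classification) <- NULL
  predictions <- do.call(rbind, lapply(names(preds), function(nm) {
    data.frame(participant_id = glob$participant_id, true_label = truth,
               predicted_label = preds[[nm]], method = nm,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(group_stats = stats_tab, classification = classification,
         confusions = confusions, predictions = predictions,
         logistic_grid = gs$grid, best_logistic = gs$best,
         seed = cohort$seed),
    class = "rsvp_study_report"
  )
}

#' @export
print.rsvp_study_report <- function(x, ...) {
  cat("Group comparison:\n")
  tab <- x$group_stats
  tab[-1] <- lapply(tab[-1], function(v) if (is.numeric(v)) round(v, 2) else v)
  print(tab, row.names = FALSE)
  cat("\nClassification:\n")
  cls <- x$classification
  cls[-1] <- lapply(cls[-1], round, 2)
  print(cls, row.names = FALSE)
  cat(sprintf("\nSelected logistic regression: penalty %s, C = %g\n",
              x$best_logistic$penalty, x$best_logistic$c))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `report.json` (full precision) plus CSV views of the group-stats
#' and classification tables and the predictions. Rounded two-decimal
#' columns are for display; the JSON always retains full precision.
#'
#' @param report An `rsvp_study_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    seed = report$seed,
    group_stats = report$group_stats,
    classification = report$classification,
    confusions = lapply(report$confusions, function(cm) {
      cm[c("tp", "fn", "fp", "tn")]
    }),
    best_logistic = report$best_logistic,
    logistic_grid = report$logistic_grid
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$group_stats, file.path(dir, "group_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(report$classification, file.path(dir, "classification.csv"),
                   row.names = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
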