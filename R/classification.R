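# Four classification procedures: fixed literature cutoffs, the sequential
# CDT -> Phototest rule, LOOCV-learned threshold on global AM, and
# grid-searched regularized logistic regression under LOOCV.

#' Fixed-threshold classification
#'
#' A participant is classified CI when the score is strictly below the
#' cutoff ("below the threshold") and HC otherwise, so a boundary score
#' classifies HC. Literature screening cutoffs: 6 for the CDT, 29 for the
#' Phototest.
#'
#' @param score Numeric vector of scores.
#' @param cutoff Decision threshold.
#' @return Character vector of `"CI"`/`"HC"` labels.
#' @examples
#' threshold_predict(c(5, 6, 7), 6) # "CI" "HC" "HC"
#' @export
threshold_predict <- function(score, cutoff) {
  if (!is.finite(cutoff) && !cutoff %in% c(-Inf, Inf)) {
    stop_rsvp("cutoff must be a number (or +/-Inf sentinel)", "invalid_cutoff")
  }
  ifelse(score < cutoff, "CI", "HC")
}

#' Sequential CDT -> Phototest classification
#'
#' The CDT is considered first: a score below its cutoff classifies CI.
#' Otherwise the Phototest is considered: a score below its cutoff
#' classifies CI, else HC. This mimics a screening examination in which the
#' quicker test gates the longer one.
#'
#' @param cdt_score,phototest_score Numeric vectors (recycled together).
#' @param cdt_cutoff,phototest_cutoff Cutoffs (defaults 6 and 29).
#' @return Character vector of `"CI"`/`"HC"` labels.
#' @examples
#' sequential_predict(c(5, 7, 7), c(45, 25, 40)) # "CI" "CI" "HC"
#' @export
sequential_predict <- function(cdt_score, phototest_score,
                               cdt_cutoff = 6, phototest_cutoff = 29) {
  ifelse(cdt_score < cdt_cutoff, "CI",
         ifelse(phototest_score < phototest_cutoff, "CI", "HC"))
}

#' Fit the training-accuracy-optimal threshold
#'
#' Scans candidate cutoffs — midpoints between consecutive distinct sorted
#' scores plus -Inf and +Inf sentinels — and returns the one maximizing
#' training accuracy under the strict-below rule (`score < cutoff` => CI).
#' Ties are broken toward the smallest optimal cutoff.
#'
#' @param scores Numeric training scores.
#' @param labels `"CI"`/`"HC"` labels aligned with `scores`.
#' @return List with `cutoff` and `train_accuracy`.
#' @examples
#' fit_optimal_threshold(c(10, 20, 50, 60), c("CI", "CI", "HC", "HC"))$cutoff # 35
#' @export
fit_optimal_threshold <- function(scores, labels) {
  labels <- assert_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop_rsvp("training data must contain both classes", "single_class")
  }
  s <- sort(unique(scores))
  candidates <- c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  acc <- vapply(candidates, function(ct) {
    mean(threshold_predict(scores, ct) == labels)
  }, numeric(1))
  best <- which(acc >= max(acc) - 1e-12)[1L]  # smallest optimal cutoff
  list(cutoff = candidates[best], train_accuracy = acc[best])
}

#' Leave-one-out cross-validated threshold classification
#'
#' For each participant i, the accuracy-optimal threshold is fitted on all
#' other participants and used to predict participant i, so no fold ever
#' sees its own holdout. Used with global attentional-masking scores this
#' is the threshold-based RSVP classifier.
#'
#' @param scores Numeric scores, one per participant.
#' @param labels `"CI"`/`"HC"` labels.
#' @return An object of class `rsvp_loocv`: list with `predictions`
#'   (character, participant order), `fold_fits` (per-fold list of
#'   `cutoff`/`train_accuracy`), `accuracy` (LOOCV accuracy), `method`.
#' @export
loocv_threshold <- function(scores, labels) {
  labels <- assert_labels(labels)
  n <- length(scores)
  if (n < 3L) stop_rsvp("LOOCV requires n >= 3", "too_few_observations")
  fold_fits <- vector("list", n)
  predictions <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_optimal_threshold(scores[-i], labels[-i])
    fold_fits[[i]] <- fit
    predictions[i] <- threshold_predict(scores[i], fit$cutoff)
  }
  structure(
    list(predictions = predictions, fold_fits = fold_fits,
         accuracy = mean(predictions == labels), method = "loocv_threshold"),
    class = "rsvp_loocv"
  )
}

#' Penalized logistic regression fit
#'
#' Penalized maximum-likelihood logistic regression with an l1 (lasso) or
#' l2 (ridge) penalty that excludes the intercept. `c` is the inverse
#' regularization strength: the fit minimizes
#' `(1/n) * deviance/2 + penalty / (c * n)`, so larger `c` means weaker
#' shrinkage. With `standardize = TRUE` (default) features are z-scored
#' using the training data's own mean and standard deviation (zero-variance
#' columns are left unscaled); the stored centering is applied again at
#' prediction time. The optimizer is coordinate descent (glmnet) with
#' convergence threshold 1e-8; non-convergence raises a named error
#' carrying the iteration count.
#'
#' @param features Numeric matrix (rows = participants).
#' @param labels `"CI"`/`"HC"` labels; CI is the positive class.
#' @param penalty `"l1"` or `"l2"`.
#' @param c Inverse regularization strength, > 0.
#' @param standardize Z-score features with training statistics?
#' @return An object of class `rsvp_logistic` with `coefficients` (on the
#'   original feature scale), `intercept`, `penalty`, `c`, `center`,
#'   `scale`. Predict with [predict.rsvp_logistic()]: the label whose
#'   probability exceeds 0.5.
#' @export
fit_logistic <- function(features, labels, penalty = c("l2", "l1"), c = 1,
                         standardize = TRUE) {
  penalty <- match.arg(penalty)
  labels <- assert_labels(labels)
  features <- as.matrix(features)
  if (c <= 0) stop_rsvp("c must be > 0", "invalid_config")
  if (length(unique(labels)) < 2L) {
    stop_rsvp("training data must contain both classes", "single_class")
  }
  if (min(table(labels)) < 2L) {
    stop_rsvp("need at least 2 rows per class", "single_class")
  }
  if (anyNA(features)) stop_rsvp("features contain undefined values", "undefined_feature")
  n <- nrow(features)
  if (standardize) {
    center <- colMeans(features)
    scl <- apply(features, 2L, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
  } else {
    center <- rep(0, ncol(features))
    scl <- rep(1, ncol(features))
  }
  x <- sweep(sweep(features, 2L, center), 2L, scl, "/")
  y <- as.integer(labels == "CI")
  lambda <- 1 / (c * n)
  fit <- withCallingHandlers(
    glmnet::glmnet(
      x, y, family = "binomial",
      alpha = if (penalty == "l1") 1 else 0,
      lambda = lambda, standardize = FALSE, intercept = TRUE,
      thresh = 1e-8, maxit = 1e5
    ),
    # routine small-sample note from the solver, not a fit failure
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (fit$npasses >= 1e5 || fit$jerr != 0) {
    stop_rsvp(sprintf("logistic fit did not converge (%d passes)", fit$npasses),
              "non_convergence")
  }
  beta_std <- as.numeric(fit$beta)
  structure(
    list(
      coefficients = beta_std / scl,   # original-scale slopes
      intercept = as.numeric(fit$a0) - sum(beta_std * center / scl),
      penalty = penalty, c = c,
      center = center, scale = scl, npasses = fit$npasses
    ),
    class = "rsvp_logistic"
  )
}

#' @rdname fit_logistic
#' @param object An `rsvp_logistic` fit.
#' @param newdata Numeric matrix of features.
#' @param type `"label"` (default) or `"prob"` (probability of CI).
#' @param ... Unused.
#' @export
predict.rsvp_logistic <- function(object, newdata, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  eta <- as.numeric(newdata %*% object$coefficients) + object$intercept
  p <- stats::plogis(eta)
  if (type == "prob") return(p)
  ifelse(p > 0.5, "CI", "HC")
}

#' Leave-one-out cross-validation of a logistic specification
#'
#' @param features Numeric matrix (rows = participants).
#' @param labels `"CI"`/`"HC"` labels.
#' @param penalty,c,standardize Passed to [fit_logistic()] per fold;
#'   standardization statistics are recomputed inside every training fold
#'   so the holdout never leaks into the fit.
#' @return An `rsvp_loocv` object (`predictions`, `fold_fits`, `accuracy`).
#' @export
loocv_logistic <- function(features, labels, penalty = "l2", c = 1,
                           standardize = TRUE) {
  labels <- assert_labels(labels)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3L) stop_rsvp("LOOCV requires n >= 3", "too_few_observations")
  predictions <- character(n)
  fold_fits <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- fit_logistic(features[-i, , drop = FALSE], labels[-i],
                        penalty = penalty, c = c, standardize = standardize)
    fold_fits[[i]] <- list(penalty = penalty, c = c,
                           intercept = fit$intercept,
                           coefficients = fit$coefficients)
    predictions[i] <- predict(fit, features[i, , drop = FALSE])
  }
  structure(
    list(predictions = predictions, fold_fits = fold_fits,
         accuracy = mean(predictions == labels), method = "loocv_logistic"),
    class = "rsvp_loocv"
  )
}

#' Grid-searched logistic regression under LOOCV
#'
#' Runs leave-one-out cross-validation for every (penalty, c) combination
#' in the grid — defaults: both penalties crossed with
#' c = 10^-7, 10^-6, ..., 10^7, i.e. 30 combinations — and selects the
#' combination with the highest LOOCV accuracy. Ties are broken toward the
#' stronger penalty (smaller c), then l2 before l1. The selected
#' combination's LOOCV predictions and accuracy are returned together with
#' the full grid table. A grid point whose folds fail to fit is recorded
#' with accuracy `NA` and excluded from selection.
#'
#' @param features Numeric matrix (rows = participants).
#' @param labels `"CI"`/`"HC"` labels.
#' @param penalties Character vector of penalties to try.
#' @param c_values Numeric vector of inverse regularization strengths.
#' @param standardize Passed to [fit_logistic()].
#' @return List with `best` (list `penalty`, `c`), `loocv` (the selected
#'   `rsvp_loocv`), `accuracy`, and `grid` (data frame `penalty`, `c`,
#'   `accuracy`).
#' @export
grid_search_loocv <- function(features, labels,
                              penalties = c("l1", "l2"),
                              c_values = 10^(-7:7),
                              standardize = TRUE) {
  if (length(penalties) == 0L || length(c_values) == 0L) {
    stop_rsvp("grid must be non-empty", "invalid_config")
  }
  grid <- expand.grid(penalty = penalties, c = c_values,
                      stringsAsFactors = FALSE)
  runs <- vector("list", nrow(grid))
  acc <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    runs[[g]] <- tryCatch(
      loocv_logistic(features, labels, penalty = grid$penalty[g],
                     c = grid$c[g], standardize = standardize),
      rsvp_error = function(e) NULL
    )
    if (!is.null(runs[[g]])) acc[g] <- runs[[g]]$accuracy
  }
  if (all(is.na(acc))) {
    stop_rsvp("no grid point produced a valid LOOCV run", "non_convergence")
  }
  # selection: max accuracy; ties -> smaller c, then l2 before l1
  ord <- order(-acc, grid$c, match(grid$penalty, c("l2", "l1")), na.last = TRUE)
  best <- ord[1L]
  list(
    best = list(penalty = grid$penalty[best], c = grid$c[best]),
    loocv = runs[[best]],
    accuracy = acc[best],
    grid = cbind(grid, accuracy = acc)
  )
}
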