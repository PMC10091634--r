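test_that("fixed thresholds classify strictly-below scores as CI", {
  expect_equal(threshold_predict(5, 6), "CI")
  expect_equal(threshold_predict(6, 6), "HC")   # boundary is HC
  expect_equal(threshold_predict(29, 29), "HC")
  expect_equal(threshold_predict(41, 29), "HC")
  # monotone: raising a score never flips HC -> CI
  scores <- seq(0, 50, by = 0.5)
  preds <- threshold_predict(scores, 29)
  expect_false(any(preds[-1] == "CI" & preds[-length(preds)] == "HC"))
})

test_that("the sequential rule gates the Phototest behind the CDT", {
  expect_equal(sequential_predict(5, 45), "CI")   # fails CDT gate
  expect_equal(sequential_predict(7, 25), "CI")   # passes CDT, fails Phototest
  expect_equal(sequential_predict(7, 40), "HC")   # passes both

  # the sequential CI set contains the CDT-only CI set
  set.seed(21)
  cdt <- sample(0:7, 200, replace = TRUE)
  photo <- sample(0:50, 200, replace = TRUE)
  cdt_only <- threshold_predict(cdt, 6)
  seq_pred <- sequential_predict(cdt, photo)
  expect_true(all(seq_pred[cdt_only == "CI"] == "CI"))
})

test_that("the fitted threshold maximizes training accuracy with the smallest-cutoff tie-break", {
  fit <- fit_optimal_threshold(c(10, 20, 50, 60), c("CI", "CI", "HC", "HC"))
  expect_equal(fit$cutoff, 35)
  expect_equal(fit$train_accuracy, 1)

  # degenerate all-identical scores: accuracy = majority class, cutoff = -Inf
  fit2 <- fit_optimal_threshold(rep(4, 5), c("HC", "HC", "HC", "CI", "CI"))
  expect_equal(fit2$train_accuracy, 0.6)
  expect_equal(fit2$cutoff, -Inf)

  expect_error(fit_optimal_threshold(1:3, c("CI", "CI", "CI")),
               class = "rsvp_error_single_class")

  set.seed(31)
  for (rep in 1:100) {
    n <- sample(4:14, 1)
    scores <- sample(0:9, n, replace = TRUE)
    labels <- sample(c("CI", "HC"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    fit <- fit_optimal_threshold(scores, labels)
    expect_equal(fit$train_accuracy, oracle_best_threshold_accuracy(scores, labels))
    expect_equal(mean(threshold_predict(scores, fit$cutoff) == labels),
                 fit$train_accuracy)
  }
})

test_that("LOOCV threshold classification predicts each holdout from the rest", {
  scores <- c(10, 12, 15, 48, 52, 60)
  labels <- c("CI", "CI", "CI", "HC", "HC", "HC")
  cv <- loocv_threshold(scores, labels)
  expect_length(cv$predictions, 6)
  expect_length(cv$fold_fits, 6)
  expect_equal(cv$predictions, labels)  # separable data: all correct
  expect_equal(cv$accuracy, 1)
  expect_error(loocv_threshold(1:2, c("CI", "HC")),
               class = "rsvp_error_too_few_observations")
})

test_that("held-out data never leaks into its own fold", {
  coh <- fixture_cohort(seed = 8)
  glob <- participant_globals(coh)
  scores <- glob$global_am
  labels <- glob$group
  cv <- loocv_threshold(scores, labels)
  fm <- build_feature_matrix(coh)
  lr <- loocv_logistic(fm$features, fm$labels, penalty = "l2", c = 1e2)
  for (i in c(1, 10, 22)) {
    mutated <- scores
    mutated[i] <- mutated[i] + 1000
    cv_mut <- loocv_threshold(mutated, labels)
    expect_identical(cv_mut$fold_fits[[i]], cv$fold_fits[[i]])

    feat_mut <- fm$features
    feat_mut[i, ] <- feat_mut[i, ] + 50
    lr_mut <- loocv_logistic(feat_mut, fm$labels, penalty = "l2", c = 1e2)
    expect_equal(lr_mut$fold_fits[[i]], lr$fold_fits[[i]])
  }
})

test_that("near-unpenalized logistic regression separates separable data", {
  x <- cbind(f1 = c(0, 1, 0.5, 9, 10, 9.5), f2 = c(1, 0, 0.5, 9, 10, 9.5))
  y <- c("CI", "CI", "CI", "HC", "HC", "HC")
  fit <- fit_logistic(x, y, penalty = "l2", c = 1e5)
  expect_equal(predict(fit, x), y)
  fit1 <- fit_logistic(x, y, penalty = "l1", c = 1e5)
  expect_equal(predict(fit1, x), y)
})

test_that("strong regularization collapses predictions to the majority class", {
  set.seed(61)
  x <- matrix(rnorm(40), ncol = 2)
  y <- c(rep("CI", 13), rep("HC", 7))
  fit <- fit_logistic(x, y, penalty = "l2", c = 1e-7)
  expect_true(all(abs(fit$coefficients) < 1e-3))
  expect_true(all(predict(fit, x) == "CI"))  # majority class
})

test_that("logistic fits recover known coefficients at large n", {
  set.seed(71)
  n <- 2000
  x <- cbind(a = rnorm(n), b = rnorm(n))
  beta <- c(1.5, -2)
  eta <- 0.5 + x %*% beta
  y <- ifelse(runif(n) < plogis(eta), "CI", "HC")
  fit <- fit_logistic(x, y, penalty = "l2", c = 1e5, standardize = FALSE)
  expect_lt(max(abs(fit$coefficients - beta) / abs(beta)), 0.1)
  expect_lt(abs(fit$intercept - 0.5) / 0.5, 0.3)
  # agreement with an unpenalized glm fit
  ref <- glm(I(y == "CI") ~ x, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]), tolerance = 0.02)
})

test_that("logistic preconditions are enforced", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_logistic(x, rep("CI", 10)), class = "rsvp_error_single_class")
  expect_error(fit_logistic(x, c(rep("CI", 9), "HC")),
               class = "rsvp_error_single_class")
  xna <- x; xna[1, 1] <- NA
  expect_error(fit_logistic(xna, c(rep("CI", 5), rep("HC", 5))),
               class = "rsvp_error_undefined_feature")
  expect_error(fit_logistic(x, c(rep("CI", 5), rep("HC", 5)), c = 0),
               class = "rsvp_error_invalid_config")
})

test_that("grid search selects the best LOOCV accuracy over the full grid", {
  fm <- build_feature_matrix(fixture_cohort(seed = 8))
  grid <- expand.grid(penalty = c("l1", "l2"), c = 10^(-7:7))
  expect_equal(nrow(grid), 30L)  # 2 penalties x 15 C values

  # small sub-grid for the exhaustive comparison
  penalties <- c("l1", "l2")
  c_values <- 10^c(-3, 0, 3)
  gs <- grid_search_loocv(fm$features, fm$labels, penalties, c_values)
  expect_equal(nrow(gs$grid), 6L)
  for (g in seq_len(nrow(gs$grid))) {
    single <- loocv_logistic(fm$features, fm$labels,
                             penalty = gs$grid$penalty[g], c = gs$grid$c[g])
    expect_gte(gs$accuracy, single$accuracy)
    expect_equal(gs$grid$accuracy[g], single$accuracy)
  }
  expect_true(gs$best$c %in% c_values)

  one <- grid_search_loocv(fm$features, fm$labels, "l2", 1)
  expect_equal(one$best, list(penalty = "l2", c = 1))
  expect_error(grid_search_loocv(fm$features, fm$labels, character(0), 1),
               class = "rsvp_error_invalid_config")
})

test_that("grid ties break toward stronger penalty and l2 before l1", {
  # perfectly separable scores make many grid points tie at accuracy 1
  x <- cbind(f1 = c(1, 2, 3, 101, 102, 103), f2 = c(3, 2, 1, 99, 98, 97))
  y <- c(rep("CI", 3), rep("HC", 3))
  gs <- grid_search_loocv(x, y, c("l1", "l2"), c(1e2, 1e4))
  tied <- gs$grid[gs$grid$accuracy == max(gs$grid$accuracy, na.rm = TRUE), ]
  expect_equal(gs$best$c, min(tied$c))
  expect_equal(gs$best$penalty, "l2")
})
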