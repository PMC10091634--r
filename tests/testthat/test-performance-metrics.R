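test_that("curve counts and conditionals follow their definitions", {
  # per separation: 10 trials, T1 correct in 8, T2 correct in 7, both in 6
  oc <- make_outcomes(10, both = 6, t1_only = 2, t2_only = 1, seps = 0)
  cv <- compute_curve(oc)
  expect_equal(cv$n_trials, 10)
  expect_equal(cv$n_t1, 8)
  expect_equal(cv$n_t2, 7)
  expect_equal(cv$n_both, 6)
  expect_equal(cv$ab, 0.75)
  expect_equal(cv$am, 6 / 7)

  all_correct <- make_outcomes(10, both = 10, t1_only = 0, t2_only = 0)
  cva <- compute_curve(all_correct)
  expect_true(all(cva$ab == 1) && all(cva$am == 1))

  # zero denominators yield NA, not 0
  none_t1 <- make_outcomes(5, both = 0, t1_only = 0, t2_only = 2, seps = 0)
  cvn <- compute_curve(none_t1)
  expect_true(is.na(cvn$ab))
  expect_equal(cvn$am, 0)

  expect_error(compute_curve(data.frame()), class = "rsvp_error_empty_outcomes")
})

test_that("curve estimates equal brute-force conditional frequencies", {
  set.seed(101)
  for (rep in 1:20) {
    oc <- data.frame(
      participant_id = "P1",
      trial_id = 1:70,
      separation = rep(rsvp_separations(), each = 10),
      t1_correct = runif(70) < 0.6,
      t2_correct = runif(70) < 0.5
    )
    cv <- compute_curve(oc)
    for (s in rsvp_separations()) {
      expected <- oracle_conditionals(oc, s)
      row <- cv[cv$separation == s, ]
      expect_equal(row$ab, expected$ab)
      expect_equal(row$am, expected$am)
    }
  }
})

test_that("increasing n_both with fixed denominators increases ab and am", {
  lo <- compute_curve(make_outcomes(10, both = 3, t1_only = 4, t2_only = 3, seps = 0))
  hi <- compute_curve(make_outcomes(10, both = 5, t1_only = 2, t2_only = 1, seps = 0))
  expect_identical(c(lo$n_t1, lo$n_t2), c(hi$n_t1, hi$n_t2))
  expect_lt(lo$ab, hi$ab)
  expect_lt(lo$am, hi$am)
})

test_that("global metrics average separations 0-2 only, on a 0-100 scale", {
  oc <- rbind(
    make_outcomes(12, both = 4, t1_only = 2, t2_only = 6, seps = 0),
    make_outcomes(12, both = 5, t1_only = 2, t2_only = 5, seps = 1),
    make_outcomes(12, both = 6, t1_only = 2, t2_only = 4, seps = 2),
    make_outcomes(12, both = 1, t1_only = 11, t2_only = 0, seps = c(4, 5, 6, 8))
  )
  g <- compute_global(compute_curve(oc))
  # am = 4/10, 5/10, 6/10 at seps 0,1,2 -> 50; larger separations ignored
  expect_equal(g$global_am, 50)
  expect_equal(g$global_ab, 100 * mean(c(4 / 6, 5 / 7, 6 / 8)))
  expect_equal(g$global_am, 100 * mean(c(4 / 10, 5 / 10, 6 / 10)))

  allc <- compute_curve(make_outcomes(10, both = 10, t1_only = 0, t2_only = 0))
  expect_equal(compute_global(allc)$global_ab, 100)
})

test_that("global metrics error on undefined or missing separations", {
  oc <- rbind(
    make_outcomes(5, both = 0, t1_only = 0, t2_only = 2, seps = 0), # no T1 correct
    make_outcomes(5, both = 3, t1_only = 1, t2_only = 1, seps = c(1, 2))
  )
  err <- expect_error(compute_global(compute_curve(oc)),
                      class = "rsvp_error_undefined_global")
  expect_match(conditionMessage(err), "0")

  missing_sep <- make_outcomes(5, both = 3, t1_only = 1, t2_only = 1, seps = c(0, 1))
  expect_error(compute_global(compute_curve(missing_sep)),
               class = "rsvp_error_undefined_global")
})

test_that("feature matrix has one row per participant and 14 ordered columns", {
  coh <- fixture_cohort(seed = 8)
  fm <- build_feature_matrix(coh)
  expect_equal(dim(fm$features), c(22L, 14L))
  expect_equal(colnames(fm$features),
               c(paste0("ab_", rsvp_separations()), paste0("am_", rsvp_separations())))
  expect_equal(fm$labels, coh$participants$group)
  expect_equal(rownames(fm$features), coh$participants$participant_id)

  # a fully correct participant contributes a row of fourteen 1s
  perfect <- list(
    participants = data.frame(participant_id = "P1", group = "HC",
                              cdt_score = 7, phototest_score = 45),
    outcomes = make_outcomes(10, both = 10, t1_only = 0, t2_only = 0)
  )
  expect_equal(unname(build_feature_matrix(perfect)$features[1, ]), rep(1, 14))
})

test_that("undefined features impute 0 with a warning naming the cell", {
  oc <- rbind(
    make_outcomes(5, both = 0, t1_only = 0, t2_only = 0, seps = 0), # all wrong
    make_outcomes(5, both = 3, t1_only = 1, t2_only = 1,
                  seps = setdiff(rsvp_separations(), 0))
  )
  oc$participant_id <- "P7"
  coh <- list(
    participants = data.frame(participant_id = "P7", group = "CI",
                              cdt_score = 4, phototest_score = 20),
    outcomes = oc
  )
  expect_warning(fm <- build_feature_matrix(coh), "P7")
  expect_equal(unname(fm$features[1, c("ab_0", "am_0")]), c(0, 0))
})

test_that("estimates converge to the generating conditionals at large n", {
  cfg <- cohort_config(trials_per_separation = 10000, seed = 404)
  set.seed(404)
  cond <- model_conditionals(cfg$model)
  for (grp in c("CI", "HC")) {
    rec <- simulate_participant(grp, cfg)
    cv <- compute_curve(rec$outcomes)
    for (s in rsvp_separations()) {
      truth <- cond[cond$group == grp & cond$separation == s, ]
      row <- cv[cv$separation == s, ]
      expect_lt(abs(row$ab - truth$ab), 0.02)
      expect_lt(abs(row$am - truth$am), 0.02)
    }
  }
})
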