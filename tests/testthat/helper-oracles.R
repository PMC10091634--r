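# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's own code paths.

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# n_ci of the pooled observations to the CI group (midranks for ties).
oracle_mwu_p <- function(x_ci, x_hc) {
  pooled <- c(x_ci, x_hc)
  n <- length(pooled)
  n_ci <- length(x_ci)
  r <- rank(pooled)
  splits <- utils::combn(n, n_ci)
  u_all <- apply(splits, 2L, function(idx) {
    sum(r[idx]) - n_ci * (n_ci + 1) / 2
  })
  u_obs <- sum(r[seq_len(n_ci)]) - n_ci * (n_ci + 1) / 2
  mu <- n_ci * (n - n_ci) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Pairwise common-language effect size: P(hc > ci) + 0.5 P(hc = ci).
oracle_cles <- function(x_ci, x_hc) {
  total <- 0
  for (a in x_ci) {
    for (b in x_hc) {
      total <- total + (b > a) + 0.5 * (b == a)
    }
  }
  total / (length(x_ci) * length(x_hc))
}

# Conditional frequencies by direct filtering of an outcome table.
oracle_conditionals <- function(outcomes, s) {
  oc <- outcomes[outcomes$separation == s, ]
  t1 <- oc[oc$t1_correct, ]
  t2 <- oc[oc$t2_correct, ]
  list(
    ab = if (nrow(t1) > 0) mean(t1$t2_correct) else NA_real_,
    am = if (nrow(t2) > 0) mean(t2$t1_correct) else NA_real_
  )
}

# Best training accuracy achievable by any strict-below threshold,
# scanning every candidate cutoff including the observed scores and
# midpoints between them.
oracle_best_threshold_accuracy <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(-Inf, s, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  max(vapply(cands, function(ct) {
    mean(ifelse(scores < ct, "CI", "HC") == labels)
  }, numeric(1)))
}

# Outcome table with exact per-separation counts: n trials per separation,
# of which `both` have T1 and T2 correct, `t1_only` only T1, `t2_only`
# only T2.
make_outcomes <- function(n, both, t1_only, t2_only,
                          seps = rsvp_separations()) {
  do.call(rbind, lapply(seps, function(s) {
    t1 <- c(rep(TRUE, both + t1_only), rep(FALSE, n - both - t1_only))
    t2 <- c(rep(TRUE, both), rep(FALSE, t1_only), rep(TRUE, t2_only),
            rep(FALSE, n - both - t1_only - t2_only))
    data.frame(participant_id = "P1", trial_id = seq_len(n),
               separation = s, t1_correct = t1, t2_correct = t2)
  }))
}

# Small deterministic cohort reused by classification tests.
fixture_cohort <- function(seed = 8) {
  simulate_cohort(cohort_config(seed = seed))
}
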