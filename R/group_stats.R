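# Nonparametric two-group comparison: tie-aware Mann-Whitney U with an exact
# two-sided p-value for small samples, common-language effect size, SEM.

# Exact null distribution of the CI-sample rank sum under random assignment
# of the pooled midranks to groups. Shift-algorithm dynamic programme over
# doubled midranks (integers even with ties), equivalent to enumerating all
# choose(n, n_ci) rank assignments. Returns the two-sided p-value for the
# observed U.
exact_mwu_p <- function(ranks2, n_ci, u_obs, n_hc) {
  n <- length(ranks2)
  maxsum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n_ci)])
  # dp[k+1, s+1] = number of k-subsets of the ranks seen so far with
  # doubled-rank sum s
  dp <- matrix(0, nrow = n_ci + 1L, ncol = maxsum + 1L)
  dp[1L, 1L] <- 1
  for (i in seq_len(n)) {
    r <- ranks2[i]
    kmax <- min(i, n_ci)
    for (k in kmax:1L) {
      if (r + 1L <= maxsum + 1L) {
        src <- seq_len(maxsum + 1L - r)
        dp[k + 1L, src + r] <- dp[k + 1L, src + r] + dp[k, src]
      }
    }
  }
  counts <- dp[n_ci + 1L, ]
  # doubled rank sum s corresponds to U_ci = s/2 - n_ci(n_ci+1)/2
  sums2 <- seq_len(maxsum + 1L) - 1L
  u_vals <- sums2 / 2 - n_ci * (n_ci + 1L) / 2
  mu <- n_ci * n_hc / 2
  extreme <- abs(u_vals - mu) >= abs(u_obs - mu) - 1e-9
  sum(counts[extreme]) / sum(counts)
}

#' Mann-Whitney U test for two groups
#'
#' Tie-aware rank-sum test comparing the CI and HC samples. Midranks are
#' used, so tied cross-group pairs contribute 1/2 to U. The two-sided
#' p-value is exact — computed from the full permutation distribution of
#' rank assignments — when `n_ci + n_hc <= exact_limit`; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' The reported U is `min(u_ci, u_hc)`, the conventional tabled statistic.
#'
#' The companion effect size is the common-language effect size
#' `u_hc / (n_ci * n_hc)`: the probability that a randomly drawn HC score
#' exceeds a randomly drawn CI score, ties counted half (equivalently
#' `1 - u_reported / (n_ci * n_hc)` when HC is the superior group).
#'
#' @param x_ci,x_hc Numeric score vectors for the CI and HC groups.
#' @param exact_limit Largest pooled sample size for which the exact
#'   p-value is computed (default 25).
#' @return An object of class `rsvp_mwu`: list with `u_ci`, `u_hc`,
#'   `u_reported`, `p_two_sided`, `effect_size`, `method`
#'   (`"exact_enumeration"` or `"normal_approx"`), `n_ci`, `n_hc`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_two_sided # 0.1
#' @export
mann_whitney <- function(x_ci, x_hc, exact_limit = 25L) {
  if (length(x_ci) == 0L || length(x_hc) == 0L) {
    stop_rsvp("both samples must be non-empty", "empty_sample")
  }
  n_ci <- length(x_ci)
  n_hc <- length(x_hc)
  pooled <- c(x_ci, x_hc)
  r <- rank(pooled)
  u_ci <- sum(r[seq_len(n_ci)]) - n_ci * (n_ci + 1) / 2
  u_hc <- n_ci * n_hc - u_ci
  n <- n_ci + n_hc
  if (n <= exact_limit) {
    method <- "exact_enumeration"
    ranks2 <- as.integer(round(2 * r))
    p <- exact_mwu_p(ranks2, n_ci, u_ci, n_hc)
  } else {
    method <- "normal_approx"
    mu <- n_ci * n_hc / 2
    ties <- table(pooled)
    sigma2 <- n_ci * n_hc / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_ci - mu - sign(u_ci - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
  }
  structure(
    list(u_ci = u_ci, u_hc = u_hc, u_reported = min(u_ci, u_hc),
         p_two_sided = p, effect_size = u_hc / (n_ci * n_hc),
         method = method, n_ci = n_ci, n_hc = n_hc),
    class = "rsvp_mwu"
  )
}

#' @export
print.rsvp_mwu <- function(x, ...) {
  cat("Mann-Whitney U test (two-sided,", x$method, ")\n")
  cat(sprintf("  n_ci = %d, n_hc = %d, U = %.1f, p = %.4g, CLES = %.3f\n",
              x$n_ci, x$n_hc, x$u_reported, x$p_two_sided, x$effect_size))
  invisible(x)
}

#' Common-language effect size
#'
#' The probability that a score drawn at random from the HC sample exceeds
#' one drawn from the CI sample, with tied pairs counted 1/2:
#' `(#\{hc > ci\} + 0.5 * #\{hc = ci\}) / (n_ci * n_hc)`.
#'
#' @param x_ci,x_hc Numeric score vectors.
#' @return A number in `[0, 1]`.
#' @examples
#' cles(c(1, 2, 3), c(4, 5, 6)) # 1
#' @export
cles <- function(x_ci, x_hc) {
  if (length(x_ci) == 0L || length(x_hc) == 0L) {
    stop_rsvp("both samples must be non-empty", "empty_sample")
  }
  cmp <- outer(x_hc, x_ci, ">") + 0.5 * outer(x_hc, x_ci, "==")
  sum(cmp) / (length(x_ci) * length(x_hc))
}

#' Effect size from a reported U statistic
#'
#' Recovers the common-language effect size from the conventional reported
#' statistic `U = min(u_ci, u_hc)` and the group sizes, when the HC group
#' is the superior one: `1 - U / (n_ci * n_hc)`.
#'
#' @param u_reported Reported U, in `[0, n_ci * n_hc]` (half-integers
#'   allowed with ties).
#' @param n_ci,n_hc Group sizes.
#' @return A number in `[0, 1]`.
#' @examples
#' round(cles_from_u(16, 13, 9), 2) # 0.86
#' @export
cles_from_u <- function(u_reported, n_ci, n_hc) {
  if (u_reported < 0 || u_reported > n_ci * n_hc) {
    stop_rsvp(sprintf("u_reported must lie in [0, %d]", n_ci * n_hc),
              "invalid_u")
  }
  1 - u_reported / (n_ci * n_hc)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n-1 denominator) divided by sqrt(n).
#'
#' @param x Numeric vector of length >= 2.
#' @return A non-negative number.
#' @export
sem <- function(x) {
  if (length(x) < 2L) {
    stop_rsvp("sem requires at least 2 observations", "too_few_observations")
  }
  stats::sd(x) / sqrt(length(x))
}

#' Group-comparison table for a cohort
#'
#' One row per measure (CDT, Phototest, RSVP global AM, RSVP global AB):
#' group means with SEM, the reported U, the exact two-sided p-value, the
#' common-language effect size and a significance flag at the 5% level (no
#' multiple-testing correction is applied).
#'
#' @param cohort An `rsvp_cohort`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `test`, `mean_ci`, `sem_ci`, `mean_hc`,
#'   `sem_hc`, `p_value`, `u_value`, `effect_size`, `significant`, `method`.
#' @export
group_stats_table <- function(cohort, alpha = 0.05) {
  glob <- suppressWarnings(participant_globals(cohort, impute = TRUE))
  measures <- list(
    CDT = glob$cdt_score,
    Phototest = glob$phototest_score,
    `RSVP (global AM)` = glob$global_am,
    `RSVP (global AB)` = glob$global_ab
  )
  is_ci <- glob$group == "CI"
  rows <- lapply(names(measures), function(nm) {
    x <- measures[[nm]]
    mw <- mann_whitney(x[is_ci], x[!is_ci])
    data.frame(
      test = nm,
      mean_ci = mean(x[is_ci]), sem_ci = sem(x[is_ci]),
      mean_hc = mean(x[!is_ci]), sem_hc = sem(x[!is_ci]),
      p_value = mw$p_two_sided, u_value = mw$u_reported,
      effect_size = mw$effect_size,
      significant = mw$p_two_sided <= alpha,
      method = mw$method,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
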