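#' Pooled standard deviation of two groups
#'
#' Degrees-of-freedom-weighted pooling:
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param sd1,sd2 Group standard deviations, > 0.
#' @param n1,n2 Group sizes, each >= 2.
#' @return The pooled SD (positive scalar).
#' @export
pooled_sd <- function(sd1, sd2, n1, n2) {
  if (n1 < 2 || n2 < 2) {
    vk_stop("pooled_sd needs n1 >= 2 and n2 >= 2", class = "vk_domain_error")
  }
  if (sd1 <= 0 || sd2 <= 0) {
    vk_stop("pooled_sd needs sd1 > 0 and sd2 > 0", class = "vk_domain_error")
  }
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Cohen's d standardised mean difference
#'
#' `d = (mean1 - mean2) / pooled SD`. Because numerator and denominator
#' rescale together, d is invariant to the logarithm base used when the
#' means/SDs are log fold changes.
#'
#' @param mean1,mean2 Group means.
#' @inheritParams pooled_sd
#' @return A `vk_effect_size` list: `mean1`, `mean2`, `sd1`, `sd2`, `n1`,
#'   `n2`, `pooled_sd`, `d`.
#' @export
cohen_d <- function(mean1, mean2, sd1, sd2, n1, n2) {
  ps <- pooled_sd(sd1, sd2, n1, n2)
  structure(
    list(mean1 = mean1, mean2 = mean2, sd1 = sd1, sd2 = sd2,
         n1 = n1, n2 = n2, pooled_sd = ps, d = (mean1 - mean2) / ps),
    class = "vk_effect_size"
  )
}

#' @export
print.vk_effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (pooled SD %.3f; n = %d vs %d)\n",
              x$d, x$pooled_sd, x$n1, x$n2))
  invisible(x)
}

#' Analytic power of the two-sided pooled-variance t-test
#'
#' Closed-form power from the noncentral t distribution with
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))` and `n1 + n2 - 2` degrees
#' of freedom.
#'
#' @param d Standardised effect size.
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided significance level.
#' @return Rejection probability.
#' @export
power_t_analytic <- function(d, n1, n2, alpha = 0.05) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
}

#' Simulation-based power for a two-group comparison
#'
#' Draws `reps` pairs of normal samples with unit SD and mean separation
#' `d`, applies the chosen two-sided test at level `alpha`, and returns
#' the rejection fraction. The base samples are drawn once from `seed`
#' and the shift `d` added afterwards, so runs with the same seed share
#' random numbers across effect sizes (power is then monotone in `d` up
#' to rare sign flips of the test statistic).
#'
#' @param d True standardised mean difference.
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided significance level in (0, 1).
#' @param reps Number of simulated data sets (>= 1).
#' @param test `"t"` (pooled-variance Student t, default) or
#'   `"mann-whitney"` (exact U critical region for these sample sizes).
#' @param seed Integer seed.
#' @return A `vk_power` list: `power`, `mc_se` (binomial Monte-Carlo SE),
#'   `effect_size`, `alpha`, `n1`, `n2`, `reps`, `test`, `seed`.
#' @export
simulate_power <- function(d, n1, n2, alpha = 0.05, reps = 100L,
                           test = c("t", "mann-whitney"), seed = 1L) {
  test <- match.arg(test)
  if (reps < 1) vk_stop("reps must be >= 1", class = "vk_domain_error")
  if (alpha <= 0 || alpha >= 1) {
    vk_stop("alpha must be in (0, 1)", class = "vk_domain_error")
  }
  draws <- withr::with_seed(seed, {
    list(x1 = matrix(stats::rnorm(reps * n1), reps, n1),
         x2 = matrix(stats::rnorm(reps * n2), reps, n2))
  })
  x1 <- draws$x1 + d
  x2 <- draws$x2
  if (test == "t") {
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    reject <- abs(tstat) > stats::qt(1 - alpha / 2, n1 + n2 - 2)
  } else {
    # exact two-sided U test: precompute the null distribution once, then
    # score each replicate's U (continuous data, ties have probability 0)
    tab <- mw_null_table(n1, n2)
    total <- sum(tab)
    cum <- cumsum(tab)
    umax <- n1 * n2
    reject <- vapply(seq_len(reps), function(i) {
      u <- sum(rank(c(x1[i, ], x2[i, ]))[seq_len(n1)]) - n1 * (n1 + 1) / 2
      p_le <- cum[u + 1] / total
      p_ge <- 1 - if (u >= 1) cum[u] / total else 0
      min(1, 2 * min(p_le, p_ge)) <= alpha
    }, logical(1))
  }
  power <- mean(reject)
  structure(
    list(power = power, mc_se = sqrt(power * (1 - power) / reps),
         effect_size = d, alpha = alpha, n1 = n1, n2 = n2, reps = reps,
         test = test, seed = as.integer(seed)),
    class = "vk_power"
  )
}

#' @export
print.vk_power <- function(x, ...) {
  cat(sprintf(
    "simulated power %.3f (MC SE %.3f) for d = %g, n = %d vs %d, alpha = %g, %s test, %d reps\n",
    x$power, x$mc_se, x$effect_size, x$n1, x$n2, x$alpha, x$test, x$reps
  ))
  invisible(x)
}

#' Effect-size table for a fold-change feature set
#'
#' Convenience wrapper: for each (population, baseline, timepoint)
#' feature in a fold-change matrix, computes group means/SDs, the pooled
#' SD and Cohen's d between G1 and G2.
#'
#' @param fc Fold-change matrix from [build_fold_change_matrix()] (or a
#'   row-bound set across baselines).
#' @param patients Patient table with assigned groups.
#' @return A `data.frame` with one row per feature: group means, SDs,
#'   sizes, `pooled_sd` and `d`. Features where a group has fewer than 2
#'   patients or zero spread are dropped.
#' @export
effect_size_table <- function(fc, patients) {
  smry <- summarize_by_group(fc, patients)
  key <- c("population", "baseline", "timepoint")
  s1 <- smry[smry$group == "G1", , drop = FALSE]
  s2 <- smry[smry$group == "G2", , drop = FALSE]
  m <- merge(s1, s2, by = key, suffixes = c("1", "2"))
  ok <- m$n1 >= 2 & m$n2 >= 2 & m$sd_log_fc1 > 0 & m$sd_log_fc2 > 0
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0) return(data.frame())
  ps <- mapply(pooled_sd, m$sd_log_fc1, m$sd_log_fc2, m$n1, m$n2)
  out <- data.frame(
    population = m$population, baseline = m$baseline,
    timepoint = m$timepoint,
    mean1 = m$mean_log_fc1, mean2 = m$mean_log_fc2,
    sd1 = m$sd_log_fc1, sd2 = m$sd_log_fc2,
    n1 = m$n1, n2 = m$n2, pooled_sd = ps,
    d = (m$mean_log_fc1 - m$mean_log_fc2) / ps,
    stringsAsFactors = FALSE
  )
  out[order(match(out$population, vk_populations()), out$baseline,
            match(out$timepoint, vk_timepoints())), , drop = FALSE]
}
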