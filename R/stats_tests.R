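#' Mann-Whitney U test with exact small-sample null
#'
#' Computes the Mann-Whitney U statistic for the first sample
#' (`U = R1 - n1(n1+1)/2`, mid-ranks under ties). Without ties and with
#' `n1 + n2 <= 16`, the p-value is exact: the full null distribution of U
#' over all `choose(n1+n2, n1)` equally likely label arrangements is
#' enumerated (and cached per sample-size pair). Otherwise a normal
#' approximation with tie-corrected variance is used. Exact two-sided
#' p-values are `min(1, 2 * smaller tail)`.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends
#'   larger) or `"less"`.
#' @return A `vk_test` object: `statistic` (U), `p_value`, `method`,
#'   `exact` flag, `n1`, `n2`, `alternative`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) {
    vk_stop("both samples must be non-empty", class = "vk_domain_error")
  }
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  r <- rank(comb)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(comb) > 0
  exact <- !ties && (n1 + n2) <= 16

  if (exact) {
    tab <- mw_null_table(n1, n2)  # counts of U = 0..n1*n2
    total <- sum(tab)
    p_le <- sum(tab[seq_len(u + 1)]) / total            # P(U <= u)
    p_ge <- sum(tab[(u + 1):length(tab)]) / total       # P(U >= u)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le
    )
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(comb)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
  }
  new_vk_test(u, min(1, p), "mann-whitney", exact, n1, n2, alternative)
}

# exact null distribution of U for sample sizes (n1, n2): counts over
# U = 0..n1*n2, by complete enumeration of rank subsets; cached
mw_null_table <- function(n1, n2) {
  key <- sprintf("mw_%d_%d", n1, n2)
  if (!is.null(.vk_cache[[key]])) return(.vk_cache[[key]])
  sets <- utils::combn(n1 + n2, n1)
  us <- colSums(sets) - n1 * (n1 + 1) / 2
  tab <- tabulate(us + 1, nbins = n1 * n2 + 1)
  .vk_cache[[key]] <- tab
  tab
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests paired differences `post - pre`. Zero differences are dropped;
#' the statistic W is the sum of ranks of positive differences among the
#' m non-zero absolute differences. Without ties in the absolute
#' differences and with `m <= 14`, the p-value is exact over all `2^m`
#' equally likely sign patterns; otherwise a normal approximation with
#' tie-corrected variance is used.
#'
#' @param pre,post Paired numeric samples of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` (post tends
#'   larger than pre) or `"less"`.
#' @return A `vk_test` object (statistic W; `n1 = n2 = m`).
#' @export
wilcoxon_signed_rank <- function(pre, post,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(pre) != length(post) || length(pre) < 1) {
    vk_stop("pre and post must be non-empty samples of equal length",
            class = "vk_domain_error")
  }
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    vk_stop("all paired differences are zero: signed-rank test undefined",
            class = "vk_degenerate_error")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && m <= 14

  if (exact) {
    tab <- signrank_null_table(m)  # counts of W = 0..m(m+1)/2
    total <- 2^m
    p_le <- sum(tab[seq_len(w + 1)]) / total
    p_ge <- sum(tab[(w + 1):length(tab)]) / total
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le
    )
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
  }
  new_vk_test(w, min(1, p), "wilcoxon-signed-rank", exact, m, m, alternative)
}

# null counts of W over all 2^m sign patterns (subset sums of ranks 1..m)
signrank_null_table <- function(m) {
  key <- sprintf("sr_%d", m)
  if (!is.null(.vk_cache[[key]])) return(.vk_cache[[key]])
  wmax <- m * (m + 1) / 2
  counts <- integer(wmax + 1)
  for (s in 0:(2^m - 1)) {
    w <- sum(which(bitwAnd(s, bitwShiftL(1L, 0:(m - 1))) != 0))
    counts[w + 1] <- counts[w + 1] + 1L
  }
  .vk_cache[[key]] <- counts
  counts
}

#' Kolmogorov-Smirnov normality check with Lilliefors correction
#'
#' Computes the KS distance between the sample's empirical CDF and a
#' normal distribution with the sample's own mean and SD. Because the
#' parameters are estimated from the data, the standard KS null is wrong
#' (anti-conservative); the p-value is therefore taken from a simulated
#' Lilliefors null table: `reps` standard-normal samples of the same size
#' are drawn under an internal fixed seed, their distances computed the
#' same way, and `p = (1 + #{D* >= D}) / (reps + 1)`. Tables are cached
#' per sample size.
#'
#' @param x Numeric sample, `n >= 4`, non-constant.
#' @param reps Size of the simulated null table (default 2000).
#' @return A `vk_test` object (statistic D).
#' @export
ks_normality <- function(x, reps = 2000L) {
  n <- length(x)
  if (n < 4) vk_stop("ks_normality needs n >= 4", class = "vk_domain_error")
  s <- stats::sd(x)
  if (s == 0) {
    vk_stop("constant sample: SD is zero, normality test undefined",
            class = "vk_degenerate_error")
  }
  d <- lilliefors_distance(x)
  tab <- lilliefors_table(n, reps)
  p <- (1 + sum(tab >= d)) / (reps + 1)
  new_vk_test(d, p, "ks-lilliefors", FALSE, n, NA_integer_, "two.sided")
}

lilliefors_distance <- function(x) {
  n <- length(x)
  z <- sort(stats::pnorm(x, mean(x), stats::sd(x)))
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

lilliefors_table <- function(n, reps) {
  key <- sprintf("lf_%d_%d", n, reps)
  if (!is.null(.vk_cache[[key]])) return(.vk_cache[[key]])
  tab <- withr::with_seed(77000L + n %% 10000L, {
    vapply(seq_len(reps), function(i) {
      lilliefors_distance(stats::rnorm(n))
    }, numeric(1))
  })
  .vk_cache[[key]] <- tab
  tab
}

new_vk_test <- function(statistic, p_value, method, exact, n1, n2, alternative) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         exact = exact, n1 = n1, n2 = n2, alternative = alternative),
    class = "vk_test"
  )
}

#' @export
print.vk_test <- function(x, ...) {
  cat(sprintf("%s test (%s): statistic = %g, p = %.5g (n1 = %s, n2 = %s, %s)\n",
              x$method, if (x$exact) "exact" else "approximate",
              x$statistic, x$p_value, x$n1, x$n2, x$alternative))
  invisible(x)
}
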