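test_that("Mann-Whitney exact path reproduces worked small-sample p-values", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 arrangements as extreme
  expect_true(r$exact)

  # identical multisets: U = n1*n2/2 by symmetry (ties force approx path)
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 3 * 3 / 2)
  expect_false(r2$exact)
  expect_equal(r2$p_value, 1)
})

test_that("Mann-Whitney exact p equals enumeration and base R across tiny sizes", {
  set.seed(31)
  for (n1 in 1:5) {
    for (n2 in n1:(10 - n1)) {
      x <- rnorm(n1)
      y <- rnorm(n2)
      for (alt in c("two.sided", "greater", "less")) {
        mine <- mann_whitney(x, y, alternative = alt)
        expect_true(mine$exact)
        expect_equal(mine$p_value, brute_mw(x, y, alt))
        # exact p-values are rational with denominator choose(n1+n2, n1)
        expect_equal(mine$p_value * choose(n1 + n2, n1),
                     round(mine$p_value * choose(n1 + n2, n1)),
                     tolerance = 1e-9)
      }
      expect_equal(mann_whitney(x, y)$p_value,
                   wilcox.test(x, y, exact = TRUE)$p.value)
    }
  }
})

test_that("Mann-Whitney approximate path matches base R without continuity correction", {
  set.seed(32)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  mine <- mann_whitney(x, y)
  expect_false(mine$exact)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  # tied data: mid-ranks and tie-corrected variance
  xt <- rep(1:5, each = 3); yt <- rep(2:6, each = 2)
  mine_t <- mann_whitney(xt, yt)
  ref_t <- wilcox.test(xt, yt, exact = FALSE, correct = FALSE)
  expect_equal(mine_t$p_value, ref_t$p.value, tolerance = 1e-8)
})

test_that("signed-rank exact path reproduces worked p-values and enumeration", {
  r <- wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3), alternative = "greater")
  expect_equal(r$p_value, 1 / 8)  # only one of 2^3 sign patterns attains W=6
  expect_true(r$exact)

  r2 <- wilcoxon_signed_rank(c(0, 0), c(-2, 2))
  expect_false(r2$exact)  # tied |d|
  expect_equal(r2$p_value, 1)

  set.seed(33)
  for (m in c(3, 5, 8, 10)) {
    pre <- rnorm(m); post <- rnorm(m, 0.5)
    for (alt in c("two.sided", "greater", "less")) {
      mine <- wilcoxon_signed_rank(pre, post, alternative = alt)
      expect_true(mine$exact)
      expect_equal(mine$p_value, brute_signrank(pre, post, alt))
      expect_equal(mine$p_value * 2^m, round(mine$p_value * 2^m),
                   tolerance = 1e-9)
    }
    expect_equal(wilcoxon_signed_rank(pre, post)$p_value,
                 wilcox.test(post, pre, paired = TRUE, exact = TRUE)$p.value)
  }

  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)),
               class = "vk_degenerate_error")
})

test_that("signed-rank approximation matches base R at m = 20", {
  set.seed(34)
  pre <- rnorm(20); post <- rnorm(20, 0.3)
  mine <- wilcoxon_signed_rank(pre, post)
  expect_false(mine$exact)
  ref <- wilcox.test(post, pre, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("rank tests hold their nominal size at the study sample sizes", {
  # achievable exact level at alpha = 0.05 for n = 8 vs 7
  tab <- vasokinetics:::mw_null_table(8, 7)
  total <- sum(tab)
  p_two <- vapply(0:56, function(u) {
    min(1, 2 * min(sum(tab[1:(u + 1)]) / total,
                   sum(tab[(u + 1):57]) / total))
  }, numeric(1))
  exact_level <- sum(tab[p_two <= 0.05]) / total
  expect_lte(exact_level, 0.05)
  set.seed(35)
  rej <- mean(replicate(4000, {
    mann_whitney(rnorm(8), rnorm(7))$p_value <= 0.05
  }))
  expect_lt(abs(rej - exact_level), 0.01 + 3 * sqrt(exact_level * (1 - exact_level) / 4000))
})

test_that("Lilliefors normality check is calibrated and matches nortest", {
  # fixed-seed standard-normal samples: rejection at 0.05 stays at the
  # nominal rate (within 3 binomial SEs over 200 seeds)
  pv <- vapply(1:200, function(s) {
    withr::with_seed(4000 + s, ks_normality(rnorm(300))$p_value)
  }, numeric(1))
  expect_lte(mean(pv <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))

  # clearly non-normal data is rejected
  expect_lt(withr::with_seed(1, ks_normality(rexp(300))$p_value), 0.01)

  # agreement with the reference Lilliefors implementation
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(50, 2, 3))
    expect_lt(abs(ks_normality(x)$p_value - nortest::lillie.test(x)$p.value),
              0.05)
    expect_equal(ks_normality(x)$statistic,
                 unname(nortest::lillie.test(x)$statistic))
  }

  expect_error(ks_normality(rep(1, 10)), class = "vk_degenerate_error")
  expect_error(ks_normality(c(1, 2, 3)), class = "vk_domain_error")
})
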