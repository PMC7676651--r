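test_that("the same scenario seed reproduces bit-identical cohorts", {
  sc <- default_scenario(seed = 42L)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(a, b)
  c2 <- generate_cohort(default_scenario(seed = 43L))
  expect_false(identical(a$counts, c2$counts))
})

test_that("a no-effect scenario with zero spread collapses to the baseline count", {
  sc <- default_scenario(seed = 7L)
  sc$trajectory$mean <- 0
  sc$trajectory$sd <- 0
  sc$baseline_count_cv <- 0
  co <- generate_cohort(sc)
  expect_true(all(co$counts$count == round(sc$baseline_count_mean)))
})

test_that("group sizes and NE-dose/group consistency hold exactly", {
  sc <- default_scenario(seed = 3L)
  co <- generate_cohort(sc)
  expect_equal(sum(co$patients$group == "G1"), 8)
  expect_equal(sum(co$patients$group == "G2"), 7)
  expect_identical(assign_group(co$patients$ne_dose), co$patients$group)
  # every patient has one full series per population, all counts positive
  expect_equal(nrow(co$counts), 15 * 6 * 6)
  expect_true(all(co$counts$count >= 1))
})

test_that("invalid configurations are rejected naming the offending field", {
  sc <- default_scenario()
  bad <- sc; bad$n_group1 <- 0
  expect_error(validate_scenario(bad), "n_group1", class = "vk_config_error")
  bad <- sc; bad$timepoints <- rev(sc$timepoints)
  expect_error(validate_scenario(bad), "timepoints", class = "vk_config_error")
  bad <- sc; bad$baseline_count_mean <- -1
  expect_error(validate_scenario(bad), "baseline_count_mean")
  bad <- sc; bad$trajectory$sd[1] <- -0.1
  expect_error(validate_scenario(bad), "trajectory")
  bad <- sc; bad$trajectory <- sc$trajectory[-1, ]
  expect_error(validate_scenario(bad), "trajectory")
  bad <- sc; bad$ne_dose_params$G1["max"] <- 0.05
  expect_error(validate_scenario(bad), "ne_dose_params")
  bad <- sc
  bad$trajectory$ref[bad$trajectory$timepoint == "Sternotomy" &
                       bad$trajectory$population == "CD34"] <- "H0"
  expect_error(validate_scenario(bad), "cycle")
})

test_that("default scenario encodes the reference feature distributions", {
  sc <- default_scenario()
  expect_equal(sc$n_group1, 8L)
  expect_equal(sc$n_group2, 7L)
  tr <- sc$trajectory
  row <- function(g, tp) tr[tr$group == g & tr$population == "CD34" &
                              tr$timepoint == tp, ]
  # H0 vs sternotomy is parameterised directly
  expect_equal(row("G1", "H0")$mean, 0.68)
  expect_equal(row("G1", "H0")$sd, 0.53)
  expect_equal(row("G2", "H0")$mean, -0.50)
  expect_equal(row("G2", "H0")$sd, 0.96)
  # H0 vs post-induction composes along the anchor chain
  expect_equal(row("G1", "Sternotomy")$mean + row("G1", "H0")$mean, 1.23)
  expect_equal(sqrt(row("G1", "Sternotomy")$sd^2 + row("G1", "H0")$sd^2), 1.08)
  expect_equal(row("G2", "Sternotomy")$mean + row("G2", "H0")$mean, -0.51)
  expect_equal(sqrt(row("G2", "Sternotomy")$sd^2 + row("G2", "H0")$sd^2), 1.05)
  # 24 h vs sternotomy is parameterised directly
  expect_equal(row("G1", "H24")$mean, 0.37)
  expect_equal(row("G2", "H24")$mean, -0.09)
})

test_that("generated fold changes follow the configured distributions", {
  # one large cohort: empirical moments of the three anchored CD34 features
  sc <- default_scenario(seed = 99L)
  sc$n_group1 <- 400L
  sc$n_group2 <- 400L
  co <- generate_cohort(sc)
  targets <- list(
    list(tp = "H0", base = "B1", m = c(1.23, -0.51), s = c(1.08, 1.05)),
    list(tp = "H0", base = "B2", m = c(0.68, -0.50), s = c(0.53, 0.96)),
    list(tp = "H24", base = "B2", m = c(0.37, -0.09), s = c(0.42, 0.43))
  )
  for (t in targets) {
    fc <- build_fold_change_matrix(co$counts, t$base)
    fc <- fc[fc$population == "CD34" & fc$timepoint == t$tp, ]
    g <- co$patients$group[match(fc$patient_id, co$patients$patient_id)]
    for (i in 1:2) {
      v <- fc$log_fc[g == c("G1", "G2")[i]]
      se_m <- t$s[i] / sqrt(length(v))
      expect_lt(abs(mean(v) - t$m[i]), 3 * se_m)
      se_s <- t$s[i] / sqrt(2 * (length(v) - 1))
      expect_lt(abs(sd(v) - t$s[i]), 3 * se_s)
    }
  }
})

test_that("the patient-level random intercept cancels in fold changes", {
  sc <- default_scenario(seed = 5L)
  sc$patient_intercept_sd <- 1.0
  co <- generate_cohort(sc)
  fc <- build_fold_change_matrix(co$counts, "B2")
  fc <- fc[fc$population == "CD34" & fc$timepoint == "H0", ]
  g <- co$patients$group[match(fc$patient_id, co$patients$patient_id)]
  # dispersion stays near the configured innovation SD despite the
  # unit-SD intercept on the count scale
  expect_lt(sd(fc$log_fc[g == "G1"]), 0.53 * 2.5)
})
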