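#' Generate a synthetic cohort
#'
#' Draws a patient table and a count table from a [scenario_config()].
#' Counts are generated on the log scale: each patient gets a log-normal
#' post-induction baseline per population (mean `baseline_count_mean`,
#' CV `baseline_count_cv`), and every later time point adds an independent
#' `Normal(mean, sd)` innovation against its reference time point, per the
#' scenario's trajectory table. The resulting count is
#' `max(1, round(exp(log level)))`, so natural-log fold changes between a
#' time point and its reference are (up to integer rounding) exactly
#' normally distributed with the configured parameters.
#'
#' Norepinephrine doses are drawn uniformly inside each group's
#' configured range (G1 at or below the 0.02 mg/kg cutoff, G2 above it),
#' EuroSCORE II scores log-normally, and a small set of synthetic
#' clinical covariates (age, sex, renal failure) is attached.
#'
#' @param config A validated `vk_scenario`.
#' @return A list with elements `patients` (one row per patient:
#'   `patient_id`, `ne_dose`, `group`, `euroscore2`, `age`, `sex`,
#'   `renal_failure`) and `counts` (one row per patient x population x
#'   time point: `patient_id`, `population`, `timepoint`, `count`).
#'   The same configuration (including its seed) always returns
#'   bit-identical tables.
#' @export
generate_cohort <- function(config) {
  validate_scenario(config)
  tp <- config$timepoints
  base_tp <- tp[1L]
  n1 <- as.integer(config$n_group1)
  n2 <- as.integer(config$n_group2)
  n <- n1 + n2
  ids <- sprintf("P%02d", seq_len(n))
  grp <- rep(c("G1", "G2"), c(n1, n2))

  cv <- config$baseline_count_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config$baseline_count_mean) - sdlog^2 / 2

  withr::with_seed(config$seed, {
    ne <- numeric(n)
    rs <- numeric(n)
    for (g in c("G1", "G2")) {
      idx <- grp == g
      r <- config$ne_dose_params[[g]]
      ne[idx] <- stats::runif(sum(idx), r[["min"]], r[["max"]])
      q <- config$risk_score_params[[g]]
      rs[idx] <- stats::rlnorm(sum(idx), q[["meanlog"]], q[["sdlog"]])
    }
    age <- pmin(70L, pmax(40L, as.integer(round(stats::rnorm(n, 56, 6)))))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    renal <- stats::rbinom(n, 1L, ifelse(grp == "G1", 0.0, 0.25))
    intercept <- if (config$patient_intercept_sd > 0) {
      stats::rnorm(n, 0, config$patient_intercept_sd)
    } else {
      rep(0, n)
    }

    # log levels: patients x timepoints per population, groups stacked
    count_rows <- vector("list", length(config$populations))
    for (pi in seq_along(config$populations)) {
      pop <- config$populations[pi]
      L <- matrix(NA_real_, n, length(tp), dimnames = list(ids, tp))
      L[, base_tp] <- stats::rnorm(n, meanlog, sdlog) + intercept
      for (g in c("G1", "G2")) {
        idx <- grp == g
        rows <- config$trajectory[
          config$trajectory$group == g & config$trajectory$population == pop, ,
          drop = FALSE
        ]
        rows <- rows[order(match(rows$timepoint, tp)), , drop = FALSE]
        # fill in reference-resolved order (refs may point forward in time
        # only through already-filled nodes; chains are acyclic by validation)
        pending <- rows
        filled <- base_tp
        while (nrow(pending) > 0L) {
          ready <- pending$ref %in% filled
          for (k in which(ready)) {
            e <- pending[k, ]
            L[idx, e$timepoint] <- L[idx, e$ref] +
              stats::rnorm(sum(idx), e$mean, e$sd)
          }
          filled <- c(filled, pending$timepoint[ready])
          pending <- pending[!ready, , drop = FALSE]
        }
      }
      count_rows[[pi]] <- data.frame(
        patient_id = rep(ids, each = length(tp)),
        population = pop,
        timepoint = rep(tp, times = n),
        count = pmax(1, round(as.vector(t(exp(L))))),
        stringsAsFactors = FALSE
      )
    }
    counts <- do.call(rbind, count_rows)
    counts <- counts[order(
      match(counts$patient_id, ids),
      match(counts$population, config$populations),
      match(counts$timepoint, tp)
    ), , drop = FALSE]
    rownames(counts) <- NULL

    patients <- data.frame(
      patient_id = ids, ne_dose = ne, group = grp, euroscore2 = rs,
      age = age, sex = sex, renal_failure = renal,
      stringsAsFactors = FALSE
    )
    list(patients = patients, counts = counts)
  })
}
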