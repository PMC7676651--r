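#' Run the full analysis pipeline
#'
#' Chains the seven analysis stages on either a synthetic scenario or a
#' pair of input CSV files: (1) `simulate` (or load) the cohort,
#' (2) `features` — log fold-change matrices for the requested baselines
#' plus group summaries, (3) `test` — cross-group Mann-Whitney,
#' within-group signed-rank and per-group normality checks for the
#' feature set, (4) `effect_power` — Cohen's d per feature plus
#' simulated and analytic power, (5) `classify` — leave-one-out
#' evaluation of both classifiers per feature, (6) `permute` —
#' permutation significance for each feature with the configured
#' classifier, (7) `match` — risk-score matched subsets with a matched
#' re-run of the classification. Every stage writes a CSV into
#' `out_dir`, and a `manifest.json` records the seed, stage list,
#' per-file MD5 checksums and headline summaries. A rerun with the same
#' configuration and seed reproduces every output byte for byte.
#'
#' Stage randomness is drawn from per-stage seeds derived
#' deterministically from the global seed, so adding or re-running one
#' stage never perturbs another's random numbers.
#'
#' @param scenario A [scenario_config()] used to simulate the cohort, or
#'   `NULL` when `counts_file`/`patients_file` are given.
#' @param counts_file,patients_file Optional input CSVs (see
#'   [read_count_table()], [read_patient_table()]) used instead of
#'   simulation.
#' @param out_dir Output directory (created if needed).
#' @param baselines Subset of `c("B1", "B2", "P0")` to compute features
#'   against.
#' @param features `data.frame` with columns `population`, `timepoint`,
#'   `baseline`: the classification features. Defaults to the three
#'   discriminative CD34+ features (pump start vs B1, pump start vs B2,
#'   24 h vs B2).
#' @param permute_spec [classifier_spec()] used for the permutation
#'   stage (default logistic; boosting is considerably slower here).
#' @param reps_permutation Randomisations per feature (default 1000 for
#'   interactive use; the reference analysis uses 10000).
#' @param power_reps Simulated data sets per effect size (default 100,
#'   matching the reference analysis).
#' @param k_match Matched pairs to select (default 5).
#' @param seed Global integer seed.
#' @return The run manifest (also written to `out_dir/manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(scenario = default_scenario(),
                         counts_file = NULL, patients_file = NULL,
                         out_dir = tempfile("vasokin-run-"),
                         baselines = c("B1", "B2", "P0"),
                         features = data.frame(
                           population = "CD34",
                           timepoint = c("H0", "H0", "H24"),
                           baseline = c("B1", "B2", "B2"),
                           stringsAsFactors = FALSE
                         ),
                         permute_spec = classifier_spec("logistic"),
                         reps_permutation = 1000L,
                         power_reps = 100L,
                         k_match = 5L,
                         seed = 1L) {
  baselines <- match.arg(baselines, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(stage) {
    as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
  }
  manifest <- list(
    package = "vasokinetics",
    version = as.character(utils::packageVersion("vasokinetics")),
    seed = as.integer(seed),
    stages = character(0),
    summaries = list()
  )
  note <- function(stage, summary) {
    manifest$stages <<- c(manifest$stages, stage)
    manifest$summaries[[stage]] <<- summary
  }
  outfile <- function(name) file.path(out_dir, name)

  # 1: cohort -----------------------------------------------------------
  if (!is.null(counts_file) || !is.null(patients_file)) {
    if (is.null(counts_file) || is.null(patients_file)) {
      vk_stop("counts_file and patients_file must be given together")
    }
    counts <- read_count_table(counts_file)
    patients <- read_patient_table(patients_file)
    src <- "files"
  } else {
    scenario$seed <- stage_seed(1L)
    cohort <- generate_cohort(scenario)
    counts <- cohort$counts
    patients <- cohort$patients
    src <- "simulated"
  }
  if (any(is.na(patients$group))) {
    patients$group <- assign_group(patients$ne_dose)
  }
  write_count_table(counts, outfile("counts.csv"))
  write_patient_table(patients, outfile("patients.csv"))
  note("simulate", list(source = src, n_patients = nrow(patients),
                        n_g1 = sum(patients$group == "G1"),
                        n_g2 = sum(patients$group == "G2")))

  # 2: features ---------------------------------------------------------
  fc_all <- list()
  for (b in baselines) {
    fc_all[[b]] <- build_fold_change_matrix(counts, baseline = b)
    utils::write.csv(transform(fc_all[[b]], log_fc = format_num(log_fc)),
                     outfile(sprintf("foldchange_%s.csv", b)),
                     row.names = FALSE, quote = FALSE)
  }
  fc <- do.call(rbind, fc_all)
  features <- features[features$baseline %in% baselines, , drop = FALSE]
  if (nrow(features) == 0) {
    vk_stop("no classification feature uses a requested baseline")
  }
  smry <- summarize_by_group(fc, patients)
  num_cols <- c("mean_log_fc", "sd_log_fc", "sem")
  smry_out <- smry
  smry_out[num_cols] <- lapply(smry_out[num_cols], format_num)
  utils::write.csv(smry_out, outfile("summary.csv"),
                   row.names = FALSE, quote = FALSE)
  note("features", list(baselines = baselines, n_rows = nrow(fc)))

  feat_vec <- function(i) {
    f <- fc[fc$population == features$population[i] &
              fc$timepoint == features$timepoint[i] &
              fc$baseline == features$baseline[i], , drop = FALSE]
    f <- f[match(patients$patient_id, f$patient_id), , drop = FALSE]
    stats::setNames(f$log_fc, patients$patient_id)
  }
  feat_name <- function(i) {
    sprintf("%s:%s:%s", features$population[i], features$timepoint[i],
            features$baseline[i])
  }
  y <- as.integer(patients$group == "G2")

  # 3: group tests ------------------------------------------------------
  tests <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    v <- feat_vec(i)
    mw <- mann_whitney(v[y == 0], v[y == 1])
    rows <- data.frame(
      feature = feat_name(i), method = mw$method,
      group = "G1-vs-G2", statistic = mw$statistic, p_value = mw$p_value,
      exact = mw$exact, stringsAsFactors = FALSE
    )
    for (g in c("G1", "G2")) {
      vg <- v[patients$group == g]
      if (length(vg) >= 4 && stats::sd(vg) > 0) {
        ks <- ks_normality(vg)
        rows <- rbind(rows, data.frame(
          feature = feat_name(i), method = ks$method, group = g,
          statistic = ks$statistic, p_value = ks$p_value, exact = ks$exact,
          stringsAsFactors = FALSE
        ))
      }
    }
    rows
  }))
  # paired within-group shift of log counts vs the baseline time point,
  # for the featured population/time point pairs
  for (i in seq_len(nrow(features))) {
    b_tp <- vk_baselines()[[features$baseline[i]]]
    sub <- counts[counts$population == features$population[i], , drop = FALSE]
    for (g in c("G1", "G2")) {
      pid <- patients$patient_id[patients$group == g]
      pre <- sub$count[sub$timepoint == b_tp][
        match(pid, sub$patient_id[sub$timepoint == b_tp])]
      post <- sub$count[sub$timepoint == features$timepoint[i]][
        match(pid, sub$patient_id[sub$timepoint == features$timepoint[i]])]
      if (all(post == pre)) next
      wt <- wilcoxon_signed_rank(log(pre), log(post))
      tests <- rbind(tests, data.frame(
        feature = feat_name(i), method = wt$method, group = g,
        statistic = wt$statistic, p_value = wt$p_value, exact = wt$exact,
        stringsAsFactors = FALSE
      ))
    }
  }
  tests$statistic <- format_num(tests$statistic)
  tests$p_value <- format_num(tests$p_value)
  utils::write.csv(tests, outfile("tests.csv"), row.names = FALSE, quote = FALSE)
  note("test", list(n_tests = nrow(tests)))

  # 4: effect sizes and power ------------------------------------------
  es <- effect_size_table(fc[fc$population %in% features$population, ,
                             drop = FALSE], patients)
  es_out <- es
  ncols <- vapply(es_out, is.numeric, logical(1))
  es_out[ncols] <- lapply(es_out[ncols], format_num)
  utils::write.csv(es_out, outfile("effect_sizes.csv"),
                   row.names = FALSE, quote = FALSE)

  n1 <- sum(y == 0); n2 <- sum(y == 1)
  key_d <- es$d[match(
    paste(features$population, features$baseline, features$timepoint),
    paste(es$population, es$baseline, es$timepoint)
  )]
  dgrid <- c(stats::na.omit(key_d), 1.0, 1.5, 2.0)
  pw <- do.call(rbind, lapply(dgrid, function(d) {
    sim <- simulate_power(d, n1, n2, reps = power_reps,
                          seed = stage_seed(4L))
    data.frame(d = d, n1 = n1, n2 = n2, alpha = 0.05, reps = power_reps,
               power_simulated = sim$power, mc_se = sim$mc_se,
               power_analytic_t = power_t_analytic(d, n1, n2),
               stringsAsFactors = FALSE)
  }))
  pw_out <- pw
  pw_out[] <- lapply(pw_out, format_num)
  utils::write.csv(pw_out, outfile("power.csv"), row.names = FALSE, quote = FALSE)
  note("effect_power", list(n_features = nrow(es),
                            d = as.numeric(stats::na.omit(key_d))))

  # 5: classification ---------------------------------------------------
  cls <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    v <- feat_vec(i)
    do.call(rbind, lapply(c("logistic", "gbt"), function(method) {
      res <- loo_evaluate(v, y, ids = patients$patient_id,
                          spec = classifier_spec(method))
      data.frame(
        feature = feat_name(i), method = method, mae = res$mae,
        n = res$n_fits,
        misclassified = paste(res$misclassified, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }))
  }))
  cls$mae <- format_num(cls$mae)
  utils::write.csv(cls, outfile("classification.csv"),
                   row.names = FALSE, quote = FALSE)
  note("classify", list(best_mae = min(as.numeric(cls$mae))))

  # 6: permutation significance ----------------------------------------
  perm <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    pr <- permutation_p(feat_vec(i), y, spec = permute_spec,
                        reps = reps_permutation, seed = stage_seed(6L) + i)
    data.frame(
      feature = feat_name(i), method = permute_spec$method,
      scheme = pr$scheme, reps = pr$reps,
      observed_mae = pr$observed_mae, p_value = pr$p_value,
      stringsAsFactors = FALSE
    )
  }))
  perm$observed_mae <- format_num(perm$observed_mae)
  perm$p_value <- format_num(perm$p_value)
  utils::write.csv(perm, outfile("permutation.csv"),
                   row.names = FALSE, quote = FALSE)
  note("permute", list(p_values = as.numeric(perm$p_value)))

  # 7: risk-score matching ---------------------------------------------
  sc1 <- stats::setNames(
    patients$euroscore2[patients$group == "G1"],
    patients$patient_id[patients$group == "G1"]
  )
  sc2 <- stats::setNames(
    patients$euroscore2[patients$group == "G2"],
    patients$patient_id[patients$group == "G2"]
  )
  mk <- min(k_match, length(sc1), length(sc2))
  mres <- match_by_score(sc1, sc2, k = mk)
  mout <- mres$pairs
  mout$distance <- format_num(mout$distance)
  utils::write.csv(mout, outfile("matched.csv"), row.names = FALSE, quote = FALSE)
  matched_ids <- c(mres$pairs$group1_id, mres$pairs$group2_id)
  sub <- patients$patient_id %in% matched_ids
  matched_mae <- if (sum(sub) >= 3 && length(unique(y[sub])) == 2) {
    loo_evaluate(feat_vec(1L)[sub], y[sub], ids = patients$patient_id[sub],
                 spec = classifier_spec("logistic"))$mae
  } else {
    NA_real_
  }
  note("match", list(k = mres$k, total_distance = mres$total_distance,
                     matched_loo_mae = matched_mae))

  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
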