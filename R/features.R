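#' Assign vasoplegia group from total norepinephrine dose
#'
#' Patients whose total norepinephrine dose stays at or below
#' 0.02 mg/kg body weight form the clinically insignificant vasoplegia
#' group G1; doses strictly above the cutoff define the clinically
#' significant group G2. The boundary dose 0.02 maps to G1 because the
#' significant group is defined by exceeding the cutoff.
#'
#' @param ne_dose Numeric vector of total norepinephrine doses (mg/kg),
#'   all >= 0.
#' @param cutoff Dose cutoff in mg/kg (default 0.02).
#' @return Character vector of `"G1"`/`"G2"` labels.
#' @export
assign_group <- function(ne_dose, cutoff = 0.02) {
  if (!is.numeric(ne_dose) || anyNA(ne_dose)) {
    vk_stop("ne_dose must be numeric and non-missing", class = "vk_domain_error")
  }
  if (any(ne_dose < 0)) {
    vk_stop("ne_dose must be >= 0 (got %g)", min(ne_dose),
            class = "vk_domain_error")
  }
  ifelse(ne_dose <= cutoff, "G1", "G2")
}

#' Natural-log fold change of a count against a baseline count
#'
#' Returns `ln((count + pc) / (baseline_count + pc))` where the
#' pseudocount `pc` equals `pseudocount` when either count is zero and 0
#' otherwise, so strictly positive counts are left untouched. Flow
#' cytometry can legitimately record zero events for a rare phenotype;
#' the pseudocount keeps such points finite.
#'
#' @param count,baseline_count Non-negative counts (cells per 10^6
#'   lympho-monocytic events); vectors are recycled as usual.
#' @param pseudocount Pseudocount applied only when a zero count is
#'   involved (default 0.5).
#' @return Numeric vector of dimensionless natural-log fold changes.
#' @export
log_fold_change <- function(count, baseline_count, pseudocount = 0.5) {
  if (any(count < 0) || any(baseline_count < 0)) {
    vk_stop("counts must be >= 0", class = "vk_domain_error")
  }
  zero <- count == 0 | baseline_count == 0
  if (any(zero & pseudocount == 0)) {
    vk_stop("log fold change undefined: zero count with pseudocount 0",
            class = "vk_domain_error")
  }
  pc <- ifelse(zero, pseudocount, 0)
  log((count + pc) / (baseline_count + pc))
}

#' Per-patient log fold-change matrix against a chosen baseline
#'
#' For every patient and population, computes the natural-log fold change
#' of each non-baseline time point's count against the count at the
#' baseline time point: B1 = post-induction, B2 = sternotomy,
#' P0 = pump start (0 h). For baseline P0 the earlier time points
#' (post-induction, sternotomy) appear as negative-lag entries. The
#' baseline time point itself never appears (its fold change is
#' identically zero).
#'
#' @param counts A validated count table (see [read_count_table()]).
#' @param baseline `"B1"`, `"B2"` or `"P0"`.
#' @param pseudocount Passed to [log_fold_change()].
#' @return A `data.frame` with columns `patient_id`, `population`,
#'   `baseline`, `timepoint`, `log_fc`; all entries finite.
#' @export
build_fold_change_matrix <- function(counts, baseline = c("B1", "B2", "P0"),
                                     pseudocount = 0.5) {
  baseline <- match.arg(baseline)
  counts <- validate_count_table(counts)
  base_tp <- vk_baselines()[[baseline]]

  base_rows <- counts[counts$timepoint == base_tp, , drop = FALSE]
  other <- counts[counts$timepoint != base_tp, , drop = FALSE]
  key <- function(d) paste(d$patient_id, d$population, sep = "\r")
  base_count <- stats::setNames(base_rows$count, key(base_rows))

  missing_base <- !key(other) %in% names(base_count)
  if (any(missing_base)) {
    ids <- sort(unique(other$patient_id[missing_base]))
    vk_stop("missing %s (baseline %s) count for patient(s): %s",
            base_tp, baseline, paste(ids, collapse = ", "),
            class = "vk_validation_error")
  }
  out <- data.frame(
    patient_id = other$patient_id,
    population = other$population,
    baseline = baseline,
    timepoint = other$timepoint,
    log_fc = log_fold_change(other$count, base_count[key(other)],
                             pseudocount = pseudocount),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Group-wise summary of log fold changes (mean and SEM)
#'
#' Summarises a fold-change matrix per (group, population, baseline,
#' time point) as n, mean and standard error of the mean
#' (SEM = sample SD / sqrt(n)). Single-patient cells report SEM 0 with
#' `degenerate_n = TRUE` so toy inputs still run end to end.
#'
#' @param fc A fold-change matrix from [build_fold_change_matrix()].
#' @param patients A patient table with assigned groups (see
#'   [read_patient_table()]); every patient in `fc` must appear with a
#'   `G1`/`G2` group.
#' @return A `data.frame` with columns `group`, `population`, `baseline`,
#'   `timepoint`, `n`, `mean_log_fc`, `sd_log_fc`, `sem`, `degenerate_n`.
#' @export
summarize_by_group <- function(fc, patients) {
  grp <- stats::setNames(patients$group, patients$patient_id)
  unknown <- setdiff(unique(fc$patient_id), patients$patient_id)
  if (length(unknown) > 0) {
    vk_stop("fold-change matrix has patient(s) absent from patient table: %s",
            paste(unknown, collapse = ", "), class = "vk_validation_error")
  }
  g <- grp[fc$patient_id]
  if (anyNA(g)) {
    vk_stop("patient(s) without assigned group: %s",
            paste(unique(fc$patient_id[is.na(g)]), collapse = ", "),
            class = "vk_validation_error")
  }
  f <- interaction(g, fc$population, fc$baseline, fc$timepoint, drop = TRUE)
  pieces <- split(fc$log_fc, f)
  meta <- do.call(rbind, strsplit(names(pieces), ".", fixed = TRUE))
  n <- vapply(pieces, length, integer(1))
  mu <- vapply(pieces, mean, numeric(1))
  sdv <- vapply(pieces, function(v) if (length(v) > 1) stats::sd(v) else 0,
                numeric(1))
  out <- data.frame(
    group = meta[, 1], population = meta[, 2], baseline = meta[, 3],
    timepoint = meta[, 4], n = n, mean_log_fc = mu, sd_log_fc = sdv,
    sem = sdv / sqrt(n), degenerate_n = n == 1L,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$group,
                   match(out$population, vk_populations()),
                   out$baseline,
                   match(out$timepoint, vk_timepoints())), , drop = FALSE]
  rownames(out) <- NULL
  out
}
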