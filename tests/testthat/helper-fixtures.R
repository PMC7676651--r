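# shared fixtures and independent brute-force oracles

# complete count table: n patients x one population x six time points,
# counts laid out so fold changes are easy to reason about
toy_counts <- function(counts_by_tp, patients = c("A", "B"),
                       population = "CD34") {
  tp <- vk_timepoints()
  stopifnot(length(counts_by_tp) == length(tp))
  do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p, population = population, timepoint = tp,
               count = counts_by_tp, stringsAsFactors = FALSE)
  }))
}

toy_patients <- function(ids, ne_dose, euroscore2 = NULL) {
  data.frame(
    patient_id = ids, ne_dose = ne_dose, group = assign_group(ne_dose),
    euroscore2 = if (is.null(euroscore2)) seq_along(ids) else euroscore2,
    stringsAsFactors = FALSE
  )
}

# 8-vs-7 labelled feature with mean separation `delta` (G1 coded 0 first)
separated_feature <- function(delta, n1 = 8, n2 = 7, sd = 1) {
  x <- c(stats::rnorm(n1, delta, sd), stats::rnorm(n2, 0, sd))
  list(x = x, y = rep(c(0L, 1L), c(n1, n2)))
}

# brute-force Mann-Whitney: enumerate every assignment of the pooled values
# to the two samples and count U (pair-count definition, not rank sums)
brute_mw <- function(x, y, alternative) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
  u_obs <- u_of(x, y)
  sets <- utils::combn(length(pool), n1)
  us <- apply(sets, 2, function(ix) u_of(pool[ix], pool[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  switch(alternative,
    two.sided = min(1, 2 * min(p_le, p_ge)),
    greater = p_ge,
    less = p_le
  )
}

# brute-force Wilcoxon signed rank: every sign pattern of the differences
brute_signrank <- function(pre, post, alternative) {
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- signs %*% r
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  switch(alternative,
    two.sided = min(1, 2 * min(p_le, p_ge)),
    greater = p_ge,
    less = p_le
  )
}

# all permutations of 1..n as a matrix (one per row)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# exhaustive-search optimum for k-pair matching (subset x subset x
# assignment), independent of the sortedness argument used by the DP
brute_match_cost <- function(s1, s2, k, caliper = Inf) {
  best <- Inf
  pm <- perms(k)
  sub1 <- utils::combn(length(s1), k, simplify = FALSE)
  sub2 <- utils::combn(length(s2), k, simplify = FALSE)
  for (a in sub1) {
    va <- s1[a]
    for (b in sub2) {
      vb <- s2[b]
      costs <- abs(matrix(va[pm], nrow(pm), k) -
                     matrix(vb, nrow(pm), k, byrow = TRUE))
      ok <- rowSums(costs > caliper) == 0
      if (any(ok)) best <- min(best, min(rowSums(costs)[ok]))
    }
  }
  best
}

# CD34 feature vector (chosen baseline/timepoint) and labels for a cohort
cohort_feature <- function(cohort, timepoint = "H0", baseline = "B1") {
  fc <- build_fold_change_matrix(cohort$counts, baseline)
  fc <- fc[fc$population == "CD34" & fc$timepoint == timepoint, , drop = FALSE]
  v <- stats::setNames(fc$log_fc, fc$patient_id)[cohort$patients$patient_id]
  list(x = unname(v), y = as.integer(cohort$patients$group == "G2"),
       ids = cohort$patients$patient_id)
}
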