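#' Optimal risk-score pair matching between two groups
#'
#' Selects `k` one-to-one cross-group pairs minimising the total absolute
#' difference in risk score (EuroSCORE II estimated % mortality in the
#' reference analysis). The optimum is computed exactly by dynamic
#' programming over the two score-sorted lists, using the fact that an
#' optimal matching on a line never crosses. Ties in score are ordered by
#' patient id for determinism. An optional caliper forbids pairs whose
#' score difference exceeds it; if no `k`-pair matching respects the
#' caliper, an infeasibility error reports the largest feasible `k`.
#'
#' @param scores1,scores2 Named numeric vectors (names are patient ids)
#'   of risk scores for the two groups.
#' @param k Number of pairs requested, `1 <= k <= min(n1, n2)`.
#' @param caliper Optional maximum allowed pair distance (default `Inf`).
#' @return A `vk_match` object: `pairs` (data.frame `group1_id`,
#'   `group2_id`, `distance`, sorted by distance), `k`, `total_distance`,
#'   `caliper`.
#' @export
match_by_score <- function(scores1, scores2, k, caliper = Inf) {
  if (is.null(names(scores1)) || is.null(names(scores2)) ||
      anyDuplicated(names(scores1)) || anyDuplicated(names(scores2))) {
    vk_stop("scores must be named by unique patient ids",
            class = "vk_domain_error")
  }
  n1 <- length(scores1); n2 <- length(scores2)
  if (k < 1 || k > min(n1, n2)) {
    vk_stop("k must satisfy 1 <= k <= min(%d, %d)", n1, n2,
            class = "vk_domain_error")
  }
  o1 <- order(scores1, names(scores1))
  o2 <- order(scores2, names(scores2))
  s1 <- scores1[o1]; s2 <- scores2[o2]

  # dp[i+1, j+1, m+1] = min cost pairing m pairs from first i of s1 and
  # first j of s2 (non-crossing optimal matching on sorted scores)
  dp <- array(Inf, dim = c(n1 + 1, n2 + 1, k + 1))
  dp[, , 1] <- 0
  choice <- array(0L, dim = c(n1 + 1, n2 + 1, k + 1))  # 1=skip i, 2=skip j, 3=pair
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      d <- abs(s1[i] - s2[j])
      for (m in seq_len(k)) {
        best <- dp[i, j + 1, m + 1]; ch <- 1L
        if (dp[i + 1, j, m + 1] < best) {
          best <- dp[i + 1, j, m + 1]; ch <- 2L
        }
        if (d <= caliper && dp[i, j, m] + d < best) {
          best <- dp[i, j, m] + d; ch <- 3L
        }
        dp[i + 1, j + 1, m + 1] <- best
        choice[i + 1, j + 1, m + 1] <- ch
      }
    }
  }
  if (!is.finite(dp[n1 + 1, n2 + 1, k + 1])) {
    feasible <- which(is.finite(dp[n1 + 1, n2 + 1, ])) - 1L
    vk_stop("no %d-pair matching satisfies caliper %g (largest feasible k: %d)",
            k, caliper, max(feasible), class = "vk_infeasible_error")
  }
  # reconstruct
  i <- n1; j <- n2; m <- k
  pairs <- list()
  while (m > 0) {
    ch <- choice[i + 1, j + 1, m + 1]
    if (ch == 1L) {
      i <- i - 1
    } else if (ch == 2L) {
      j <- j - 1
    } else {
      pairs[[length(pairs) + 1]] <- data.frame(
        group1_id = names(s1)[i], group2_id = names(s2)[j],
        distance = abs(s1[i] - s2[j]), stringsAsFactors = FALSE
      )
      i <- i - 1; j <- j - 1; m <- m - 1
    }
  }
  pairs <- do.call(rbind, rev(pairs))
  pairs <- pairs[order(pairs$distance, pairs$group1_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs, k = as.integer(k),
         total_distance = sum(pairs$distance), caliper = caliper),
    class = "vk_match"
  )
}

#' @export
print.vk_match <- function(x, ...) {
  cat(sprintf("risk-score matching: %d pairs, total |score difference| = %.4g\n",
              x$k, x$total_distance))
  print(x$pairs)
  invisible(x)
}
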