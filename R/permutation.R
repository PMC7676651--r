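#' Shuffle group labels preserving group sizes
#'
#' Returns a uniformly random permutation of the label vector: the
#' multiset of labels (hence both group sizes) is preserved exactly.
#' Uses the current RNG state.
#'
#' @param labels Non-empty vector of labels.
#' @return A permuted copy of `labels`.
#' @export
shuffle_labels <- function(labels) {
  if (length(labels) < 1) {
    vk_stop("labels must be non-empty", class = "vk_domain_error")
  }
  sample(labels)
}

#' Permutation significance of leave-one-out classification error
#'
#' Computes the observed leave-one-out MAE of the chosen classifier on
#' the real data, then re-runs the *entire* leave-one-out loop on each of
#' `reps` randomised data sets and reports
#' `p = #\{null MAE <= observed MAE\} / reps` — the fraction of random
#' data sets fitting as well or better. Two randomisation schemes:
#'
#' * `"label-shuffle"`: the feature is kept and the group labels are
#'   redistributed among patients, preserving both group sizes;
#' * `"uniform-feature"`: labels are kept and each patient's feature
#'   value is redrawn uniformly between the minimum and maximum of the
#'   observed feature (the more aggressive null).
#'
#' With the closed inequality and no add-one correction, `p` is an exact
#' multiple of `1/reps` and can be 0; `add_one = TRUE` switches to
#' `(1 + #\{<=\}) / (1 + reps)`, which cannot.
#'
#' @inheritParams loo_evaluate
#' @param reps Number of randomisations (>= 1; the reference analysis
#'   uses 10000).
#' @param seed Integer seed; fixes the null sample exactly.
#' @param scheme `"label-shuffle"` (default) or `"uniform-feature"`.
#' @param add_one Use the add-one small-sample correction (default off).
#' @return A `vk_permutation` object: `observed_mae`, `null_maes`,
#'   `p_value`, `reps`, `scheme`, `seed`.
#' @export
permutation_p <- function(x, y, ids = NULL, spec = classifier_spec(),
                          reps = 10000L, seed = 1L,
                          scheme = c("label-shuffle", "uniform-feature"),
                          add_one = FALSE) {
  scheme <- match.arg(scheme)
  if (reps < 1) vk_stop("reps must be >= 1", class = "vk_domain_error")
  observed <- loo_evaluate(x, y, ids = ids, spec = spec)$mae
  lo <- min(x); hi <- max(x)
  n <- length(x)
  null_maes <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      if (scheme == "label-shuffle") {
        loo_evaluate(x, shuffle_labels(y), spec = spec)$mae
      } else {
        loo_evaluate(stats::runif(n, lo, hi), y, spec = spec)$mae
      }
    }, numeric(1))
  })
  hits <- sum(null_maes <= observed)
  p <- if (add_one) (1 + hits) / (1 + reps) else hits / reps
  structure(
    list(observed_mae = observed, null_maes = null_maes, p_value = p,
         reps = as.integer(reps), scheme = scheme, seed = as.integer(seed),
         add_one = add_one),
    class = "vk_permutation"
  )
}

#' @export
print.vk_permutation <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s, %d reps): observed MAE = %.4g, p = %.4g\n",
    x$scheme, x$reps, x$observed_mae, x$p_value
  ))
  invisible(x)
}
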