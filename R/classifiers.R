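#' Classifier specification
#'
#' Bundles the hyperparameters of the two self-contained single-feature
#' classifiers. Defaults: logistic regression with a small ridge penalty
#' (keeps leave-one-out folds well defined even when a fold is linearly
#' separable), and for gradient boosting 100 rounds of depth-1 stumps
#' with shrinkage 0.1.
#'
#' @param method `"logistic"` or `"gbt"`.
#' @param l2 Ridge penalty on the logistic slope, >= 0.
#' @param rounds Boosting iterations, >= 1.
#' @param learning_rate Boosting shrinkage in (0, 1].
#' @param max_depth Tree depth, >= 1.
#' @param threshold Probability cutoff for hard labels, in (0, 1).
#' @return A `vk_classifier_spec` list.
#' @export
classifier_spec <- function(method = c("logistic", "gbt"), l2 = 1e-4,
                            rounds = 100L, learning_rate = 0.1,
                            max_depth = 1L, threshold = 0.5) {
  method <- match.arg(method)
  if (l2 < 0) vk_stop("l2 must be >= 0", class = "vk_config_error")
  if (rounds < 1) vk_stop("rounds must be >= 1", class = "vk_config_error")
  if (learning_rate <= 0 || learning_rate > 1) {
    vk_stop("learning_rate must be in (0, 1]", class = "vk_config_error")
  }
  if (max_depth < 1) vk_stop("max_depth must be >= 1", class = "vk_config_error")
  if (threshold <= 0 || threshold >= 1) {
    vk_stop("threshold must be in (0, 1)", class = "vk_config_error")
  }
  structure(
    list(method = method, l2 = l2, rounds = as.integer(rounds),
         learning_rate = learning_rate, max_depth = as.integer(max_depth),
         threshold = threshold),
    class = "vk_classifier_spec"
  )
}

#' Ridge-penalised logistic regression by IRLS
#'
#' Fits `P(y = 1 | x) = plogis(a + b x)` by maximising the Bernoulli
#' log-likelihood minus `l2/2 * b^2` (the intercept is unpenalised),
#' using Newton / iteratively reweighted least squares. Convergence is
#' declared when the largest coefficient change falls below `tol`;
#' hitting `max_iter` (which happens with `l2 = 0` on separable data,
#' where the likelihood has no finite maximiser) sets
#' `converged = FALSE`.
#'
#' @param x Numeric feature vector (n >= 2).
#' @param y 0/1 labels; both classes must be present.
#' @param l2 Ridge penalty on the slope.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return A `vk_logit` model: `intercept`, `slope`, `converged`, `l2`.
#' @export
fit_logistic <- function(x, y, l2 = 0, max_iter = 100L, tol = 1e-8) {
  check_xy(x, y)
  a <- 0; b <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- a + b * x
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    g1 <- sum(y - p)
    g2 <- sum((y - p) * x) - l2 * b
    h11 <- sum(w)
    h12 <- sum(w * x)
    h22 <- sum(w * x^2) + l2
    det <- h11 * h22 - h12^2
    if (!is.finite(det) || det <= 1e-300) break
    da <- (h22 * g1 - h12 * g2) / det
    db <- (h11 * g2 - h12 * g1) / det
    a <- a + da; b <- b + db
    if (max(abs(da), abs(db)) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(intercept = a, slope = b, converged = converged, l2 = l2),
    class = "vk_logit"
  )
}

#' @export
predict.vk_logit <- function(object, newdata, ...) {
  stats::plogis(object$intercept + object$slope * as.numeric(newdata))
}

#' Gradient-boosted regression stumps with logistic loss
#'
#' Self-contained gradient boosting for binary classification on a
#' single numeric feature. The initial score is the log-odds of the base
#' rate. Each round fits a regression tree (default depth 1) to the
#' current negative gradient: splits are found by exact scan over the
#' midpoints of sorted unique feature values, maximising the Newton gain
#' `G_L^2/H_L + G_R^2/H_R - G^2/H` with gradients `g = p - y` and
#' Hessians `h = p(1-p)`; each leaf takes the Newton step `-G/H`, scaled
#' by the learning rate. Degenerate trees (no split with positive gain,
#' e.g. a constant feature) contribute a zero root leaf, leaving the
#' prediction at the base rate.
#'
#' @param x Numeric feature vector (n >= 2).
#' @param y 0/1 labels; both classes must be present.
#' @param spec A [classifier_spec()] (fields `rounds`, `learning_rate`,
#'   `max_depth` are used).
#' @return A `vk_gbt` model: `f0`, `trees`, `spec`.
#' @export
fit_gbt <- function(x, y, spec = classifier_spec("gbt")) {
  check_xy(x, y)
  f0 <- stats::qlogis(mean(y))
  f <- rep(f0, length(x))
  trees <- vector("list", spec$rounds)
  for (r in seq_len(spec$rounds)) {
    p <- stats::plogis(f)
    g <- p - y
    h <- p * (1 - p)
    tree <- grow_tree(x, g, h, spec$max_depth)
    trees[[r]] <- tree
    f <- f + spec$learning_rate * tree_predict(tree, x)
  }
  structure(list(f0 = f0, trees = trees, spec = spec), class = "vk_gbt")
}

grow_tree <- function(x, g, h, depth) {
  G <- sum(g); H <- sum(h)
  leaf <- list(leaf = TRUE, value = if (H > 0) -G / H else 0)
  if (depth < 1 || length(x) < 2) return(leaf)
  ux <- sort(unique(x))
  if (length(ux) < 2) return(leaf)
  cuts <- (ux[-length(ux)] + ux[-1]) / 2
  score <- function(Gs, Hs) if (Hs > 0) Gs^2 / Hs else 0
  base <- score(G, H)
  best <- list(gain = 0)
  for (cut in cuts) {
    l <- x < cut
    GL <- sum(g[l]); HL <- sum(h[l])
    gain <- score(GL, HL) + score(G - GL, H - HL) - base
    if (gain > best$gain + 1e-12) best <- list(gain = gain, cut = cut)
  }
  if (best$gain <= 0) return(leaf)
  l <- x < best$cut
  list(
    leaf = FALSE, cut = best$cut,
    left = grow_tree(x[l], g[l], h[l], depth - 1),
    right = grow_tree(x[!l], g[!l], h[!l], depth - 1)
  )
}

tree_predict <- function(tree, x) {
  if (tree$leaf) return(rep(tree$value, length(x)))
  out <- numeric(length(x))
  l <- x < tree$cut
  out[l] <- tree_predict(tree$left, x[l])
  out[!l] <- tree_predict(tree$right, x[!l])
  out
}

#' @export
predict.vk_gbt <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  f <- rep(object$f0, length(x))
  for (tree in object$trees) {
    f <- f + object$spec$learning_rate * tree_predict(tree, x)
  }
  stats::plogis(f)
}

check_xy <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    vk_stop("x and y must have equal length >= 2", class = "vk_domain_error")
  }
  if (!all(y %in% c(0, 1))) {
    vk_stop("y must be 0/1 labels", class = "vk_domain_error")
  }
  if (length(unique(y)) < 2) {
    vk_stop("both classes must be present", class = "vk_domain_error")
  }
  invisible(TRUE)
}

#' Leave-one-out evaluation of a single-feature classifier
#'
#' Performs exactly n training fits, the i-th on all patients except i,
#' and predicts the held-out patient each time. Hard labels use the
#' spec's probability threshold (default 0.5), so the mean absolute
#' error equals the misclassification rate; `soft_mae = TRUE` instead
#' averages `|y - predicted probability|`. Folds whose training labels
#' collapse to one class predict the training majority class and are
#' flagged. Logistic fits that fail to converge at the spec's penalty
#' are refitted with `l2 = 1e-4` and flagged.
#'
#' @param x Numeric feature vector (n >= 3).
#' @param y 0/1 labels, both classes present.
#' @param ids Optional patient identifiers (default `"1"..."n"`).
#' @param spec A [classifier_spec()].
#' @param soft_mae Report probability-based MAE instead of hard-label MAE.
#' @param keep_models Keep each fold's fitted model (for diagnostics).
#' @return A `vk_loo` object: `predictions` (data.frame with
#'   `patient_id`, `y`, `prob`, `label`, `fold_flag`), `mae`,
#'   `misclassified`, `n_fits`, `spec`, and optionally `models`.
#' @export
loo_evaluate <- function(x, y, ids = NULL, spec = classifier_spec(),
                         soft_mae = FALSE, keep_models = FALSE) {
  n <- length(x)
  if (n < 3) vk_stop("leave-one-out needs n >= 3", class = "vk_domain_error")
  check_xy(x, y)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (length(ids) != n || anyDuplicated(ids)) {
    vk_stop("ids must be unique and match x", class = "vk_domain_error")
  }

  fast <- spec$method == "logistic" && !keep_models &&
    min(tabulate(factor(y, levels = c(0, 1)))) >= 2
  if (fast) {
    prob <- loo_logistic_fast(x, y, spec$l2)
    flags <- rep("", n)
  } else {
    prob <- numeric(n)
    flags <- character(n)
    models <- vector("list", n)
    for (i in seq_len(n)) {
      xt <- x[-i]; yt <- y[-i]
      if (length(unique(yt)) < 2) {
        prob[i] <- mean(yt)  # majority-class base rate (0 or 1)
        flags[i] <- "one-class-fold"
        models[[i]] <- NULL
        next
      }
      if (spec$method == "logistic") {
        fit <- fit_logistic(xt, yt, l2 = spec$l2)
        if (!fit$converged) {
          fit <- fit_logistic(xt, yt, l2 = 1e-4)
          flags[i] <- "ridge-fallback"
        }
      } else {
        fit <- fit_gbt(xt, yt, spec)
      }
      prob[i] <- predict(fit, x[i])
      models[[i]] <- fit
    }
  }
  label <- as.integer(prob >= spec$threshold)
  mae <- if (soft_mae) mean(abs(y - prob)) else mean(abs(y - label))
  out <- structure(
    list(
      predictions = data.frame(
        patient_id = ids, y = y, prob = prob, label = label,
        fold_flag = flags, stringsAsFactors = FALSE
      ),
      mae = mae,
      misclassified = ids[label != y],
      n_fits = n,
      spec = spec,
      soft_mae = soft_mae
    ),
    class = "vk_loo"
  )
  if (keep_models && !fast) out$models <- models
  out
}

# all-folds-at-once IRLS for single-feature ridge logistic LOO; numerically
# identical to per-fold fit_logistic (same update, tolerance and cap)
loo_logistic_fast <- function(x, y, l2, max_iter = 100L, tol = 1e-8) {
  n <- length(x)
  A <- rep(0, n); B <- rep(0, n)  # per-fold coefficients
  active <- rep(TRUE, n)
  X <- matrix(x, n, n)            # column j = data, fold j masks row j
  Y <- matrix(y, n, n)
  M <- 1 - diag(n)
  for (it in seq_len(max_iter)) {
    idx <- which(active)
    if (length(idx) == 0) break
    eta <- sweep(X[, idx, drop = FALSE], 2, B[idx], `*`)
    eta <- sweep(eta, 2, A[idx], `+`)
    P <- stats::plogis(eta)
    W <- pmax(P * (1 - P), 1e-12) * M[, idx, drop = FALSE]
    R <- (Y[, idx, drop = FALSE] - P) * M[, idx, drop = FALSE]
    g1 <- colSums(R)
    g2 <- colSums(R * X[, idx, drop = FALSE]) - l2 * B[idx]
    h11 <- colSums(W)
    h12 <- colSums(W * X[, idx, drop = FALSE])
    h22 <- colSums(W * X[, idx, drop = FALSE]^2) + l2
    det <- h11 * h22 - h12^2
    ok <- is.finite(det) & det > 1e-300
    da <- ifelse(ok, (h22 * g1 - h12 * g2) / det, 0)
    db <- ifelse(ok, (h11 * g2 - h12 * g1) / det, 0)
    A[idx] <- A[idx] + da
    B[idx] <- B[idx] + db
    done <- pmax(abs(da), abs(db)) < tol | !ok
    active[idx[done]] <- FALSE
  }
  # non-converged folds (separable at l2 = 0): per-fold ridge fallback
  if (any(active) && l2 < 1e-4) {
    for (i in which(active)) {
      fit <- fit_logistic(x[-i], y[-i], l2 = 1e-4)
      A[i] <- fit$intercept; B[i] <- fit$slope
    }
  }
  stats::plogis(A + B * x)
}

#' @export
print.vk_loo <- function(x, ...) {
  cat(sprintf(
    "leave-one-out (%s): MAE = %.4g (%d/%d misclassified%s)\n",
    x$spec$method, x$mae, length(x$misclassified), x$n_fits,
    if (x$soft_mae) "; probability MAE" else ""
  ))
  invisible(x)
}
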