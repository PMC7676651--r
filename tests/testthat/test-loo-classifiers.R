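test_that("logistic fit respects symmetry and centre-point probability", {
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  f <- fit_logistic(x, y, l2 = 1e-4)
  expect_lt(abs(f$intercept), 1e-6)
  expect_equal(predict(f, mean(x)), 0.5, tolerance = 1e-6)
  expect_true(f$converged)
  expect_error(fit_logistic(x, rep(1, 6)), class = "vk_domain_error")
})

test_that("IRLS solution maximises the penalised likelihood (grid oracle)", {
  x <- c(-1.4, -0.9, -0.6, -0.1, 0.2, 0.5, 1.1, 1.7)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  l2 <- 0.5
  f <- fit_logistic(x, y, l2 = l2)
  pen_ll <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta))) - l2 / 2 * b^2
  }
  # two-stage dense grid search, independent of the IRLS path
  coarse <- expand.grid(a = seq(-3, 3, 0.05), b = seq(-1, 5, 0.05))
  ll <- mapply(pen_ll, coarse$a, coarse$b)
  top <- coarse[which.max(ll), ]
  fine <- expand.grid(a = seq(top$a - 0.06, top$a + 0.06, 0.001),
                      b = seq(top$b - 0.06, top$b + 0.06, 0.001))
  llf <- mapply(pen_ll, fine$a, fine$b)
  best <- fine[which.max(llf), ]
  expect_lt(abs(f$intercept - best$a), 2e-3)
  expect_lt(abs(f$slope - best$b), 2e-3)
})

test_that("unpenalised logistic agrees with glm on non-separable data", {
  set.seed(4)
  x <- rnorm(20)
  y <- as.integer(plogis(0.5 + 1.2 * x) > runif(20))
  f <- fit_logistic(x, y, l2 = 0)
  g <- glm(y ~ x, family = binomial)
  expect_equal(f$intercept, unname(coef(g)[1]), tolerance = 1e-4)
  expect_equal(f$slope, unname(coef(g)[2]), tolerance = 1e-4)
})

test_that("separable data at l2 = 0 is flagged as non-converged", {
  x <- c(-2, -1, 1, 2)
  y <- c(0, 0, 1, 1)
  f <- fit_logistic(x, y, l2 = 0)
  expect_false(f$converged)
  f2 <- fit_logistic(x, y, l2 = 1e-4)
  expect_true(f2$converged)
})

test_that("boosted stumps take hand-computed Newton steps", {
  # base rate 0.5: g = +-0.5, h = 0.25; best split at 2.5 gives leaves
  # -G/H = -2 and +2; with learning rate 1 the margins are -2 and +2
  f <- fit_gbt(c(1, 2, 3, 4), c(0, 0, 1, 1),
               classifier_spec("gbt", rounds = 1, learning_rate = 1))
  expect_equal(predict(f, c(1, 2, 3, 4)),
               plogis(c(-2, -2, 2, 2)))
  expect_equal(f$f0, 0)
})

test_that("boosting has capacity for separable data and degenerates on constants", {
  x <- c(sort(runif(8)), sort(runif(7)) + 2)
  y <- rep(c(0L, 1L), c(8, 7))
  f <- fit_gbt(x, y, classifier_spec("gbt", rounds = 50, learning_rate = 0.3))
  expect_equal(as.integer(predict(f, x) >= 0.5), y)

  fc <- fit_gbt(rep(1, 10), rep(c(0L, 1L), c(4, 6)), classifier_spec("gbt"))
  expect_equal(predict(fc, c(0, 1, 2)), rep(0.6, 3))
})

test_that("boosting configuration matches the reference gradient-boosting library", {
  library(xgboost)
  spec <- classifier_spec("gbt")
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(15) + rep(c(0, 2), c(8, 7))
    y <- rep(c(0L, 1L), c(8, 7))
    mine <- predict(fit_gbt(x, y, spec), x)
    bst <- xgb.train(
      params = list(objective = "binary:logistic", eta = 0.1, max_depth = 1,
                    lambda = 0, alpha = 0, min_child_weight = 0, gamma = 0,
                    base_score = mean(y)),
      data = xgb.DMatrix(matrix(x, ncol = 1), label = y),
      nrounds = 100, verbose = 0
    )
    expect_equal(mine, predict(bst, matrix(x, ncol = 1)), tolerance = 1e-6)
  }
  # held-out predictions can differ only through tie-broken cut placement;
  # hard labels agree on >= 90% of patients on a fixed fixture
  set.seed(1)
  x <- rnorm(15) + rep(c(0, 2), c(8, 7))
  y <- rep(c(0L, 1L), c(8, 7))
  mine <- loo_evaluate(x, y, spec = spec)$predictions$prob
  xg <- vapply(1:15, function(i) {
    bst <- xgb.train(
      params = list(objective = "binary:logistic", eta = 0.1, max_depth = 1,
                    lambda = 0, alpha = 0, min_child_weight = 0, gamma = 0,
                    base_score = mean(y[-i])),
      data = xgb.DMatrix(matrix(x[-i], ncol = 1), label = y[-i]),
      nrounds = 100, verbose = 0
    )
    predict(bst, matrix(x[i], ncol = 1))
  }, numeric(1))
  expect_gte(mean((mine >= 0.5) == (xg >= 0.5)), 0.9)
})

test_that("leave-one-out performs n fits and MAE counts misclassifications", {
  set.seed(41)
  feat <- separated_feature(1.6)
  res <- loo_evaluate(feat$x, feat$y, spec = classifier_spec("logistic"))
  expect_equal(res$n_fits, 15)
  expect_equal(res$mae * 15, length(res$misclassified))
  expect_equal(res$mae * 15, round(res$mae * 15))
  resg <- loo_evaluate(feat$x, feat$y, spec = classifier_spec("gbt"),
                       keep_models = TRUE)
  expect_length(resg$models, 15)
  expect_error(loo_evaluate(c(1, 2), c(0, 1)), class = "vk_domain_error")

  soft <- loo_evaluate(feat$x, feat$y, spec = classifier_spec("logistic"),
                       soft_mae = TRUE)
  expect_equal(soft$mae, mean(abs(soft$predictions$y - soft$predictions$prob)))
})

test_that("the vectorised logistic LOO equals the per-fold loop exactly", {
  spec <- classifier_spec("logistic")
  for (s in 1:5) {
    set.seed(50 + s)
    feat <- separated_feature(runif(1, 0, 2))
    fast <- loo_evaluate(feat$x, feat$y, spec = spec)
    slow <- loo_evaluate(feat$x, feat$y, spec = spec, keep_models = TRUE)
    expect_equal(fast$predictions$prob, slow$predictions$prob)
    expect_identical(fast$predictions$label, slow$predictions$label)
  }
  # including the separable case at l2 = 0 (ridge fallback in both paths)
  x <- c(-3, -2.5, -2, -1.5, 1.5, 2, 2.5, 3)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  spec0 <- classifier_spec("logistic", l2 = 0)
  fast <- loo_evaluate(x, y, spec = spec0)
  slow <- loo_evaluate(x, y, spec = spec0, keep_models = TRUE)
  expect_equal(fast$predictions$prob, slow$predictions$prob)
})

test_that("training fold i never sees patient i's feature (no leakage)", {
  set.seed(42)
  feat <- separated_feature(1.0)
  for (method in c("logistic", "gbt")) {
    spec <- classifier_spec(method)
    base <- loo_evaluate(feat$x, feat$y, spec = spec, keep_models = TRUE)
    x2 <- feat$x
    x2[3] <- x2[3] + 50  # gross perturbation of one patient
    pert <- loo_evaluate(x2, feat$y, spec = spec, keep_models = TRUE)
    expect_identical(base$models[[3]], pert$models[[3]])
    grid <- seq(-3, 3, length.out = 7)
    expect_equal(predict(base$models[[3]], grid),
                 predict(pert$models[[3]], grid))
    # other folds do change (they train on the perturbed point)
    expect_false(isTRUE(all.equal(predict(base$models[[1]], grid),
                                  predict(pert$models[[1]], grid))))
  }
})

test_that("folds whose training labels collapse predict the majority class", {
  x <- c(0.1, 0.2, 0.3, 5)
  y <- c(0L, 0L, 0L, 1L)
  res <- loo_evaluate(x, y, spec = classifier_spec("logistic"))
  expect_equal(res$predictions$fold_flag[4], "one-class-fold")
  expect_equal(res$predictions$prob[4], 0)
})

test_that("well-separated features are classified perfectly almost always", {
  # at 6 within-group SDs of separation the per-patient error probability
  # is ~Phi(-3), so a 15-patient cohort is fully correct ~98% of the time
  zero <- vapply(1:20, function(s) {
    set.seed(600 + s)
    feat <- separated_feature(6.0)
    loo_evaluate(feat$x, feat$y, spec = classifier_spec("logistic"))$mae == 0
  }, logical(1))
  expect_gte(mean(zero), 0.95)
})
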