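test_that("stratified folds spread cases evenly and partition subjects", {
  tab <- generate_cohort(default_cohort_config(missingness_rate = 0,
                                               seed = 61L))
  fold <- make_cv_plan(tab$outcome, 10L, seed = 4L)
  expect_equal(length(fold), 598L)
  expect_true(all(table(fold[tab$outcome == 1]) == 2L))
  expect_true(all(sort(unique(fold)) == 1:10))
  expect_identical(fold, make_cv_plan(tab$outcome, 10L, seed = 4L))
  expect_false(identical(fold, make_cv_plan(tab$outcome, 10L, seed = 5L)))
  expect_error(make_cv_plan(rep(c(0, 1), c(100, 5)), 10L), "fewer cases")
})

test_that("preprocessor standardizes, imputes with training medians, and
           never re-estimates on new rows", {
  tab <- small_cohort(missingness = 0.08)
  feats <- variable_sets()$automated
  pp <- fit_preprocessor(tab, feats)
  m <- apply_preprocessor(pp, tab)
  cont <- setdiff(feats, "tpa")
  expect_true(all(abs(colMeans(m[, cont])) < 0.2))
  expect_true(all(abs(apply(m[, cont], 2, sd) - 1) < 0.25))
  expect_true(all(m[, "tpa"] %in% c(0, 1)))  # binary passthrough

  row <- tab[1, ] ; row$glucose <- NA
  v <- apply_preprocessor(pp, row)[, "glucose"]
  expected <- (pp$pars$glucose$median - pp$pars$glucose$center) /
    pp$pars$glucose$scale
  expect_equal(unname(v), expected)

  # transform parameters do not depend on rows it is applied to
  perturbed <- tab ; perturbed$glucose <- perturbed$glucose * 100
  expect_identical(pp$pars, fit_preprocessor(tab, feats)$pars)
  expect_error(fit_preprocessor(tab[tab$outcome == 0, ], feats),
               "both classes")
})

test_that("zero-variance features end with zero logistic coefficient", {
  withr::with_seed(3, {
    x <- cbind(signal = rnorm(200), flat = rep(5, 200))
    y <- as.integer(x[, 1] + rnorm(200, 0, 0.5) > 0)
  })
  pp <- fit_preprocessor(
    data.frame(signal = x[, 1], flat = x[, 2], outcome = y),
    c("signal", "flat"))
  m <- apply_preprocessor(pp, data.frame(signal = x[, 1], flat = x[, 2]))
  fit <- fit_logistic(m, y)
  expect_equal(unname(fit$coef["flat"]), 0)
  expect_gt(unname(fit$coef["signal"]), 0)
})

test_that("logistic regression separates a separable toy problem", {
  x <- matrix(c(rep(0, 20), rep(1, 20)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(x, y, model_spec("logistic", l2 = 1e-4))
  p <- predict_prob(fit, x)
  expect_equal(roc_curve(y, p)$auroc, 1)
})

test_that("csf_ratio_24h carries a negative risk coefficient", {
  tab <- generate_cohort(default_cohort_config(missingness_rate = 0,
                                               seed = 62L))
  feats <- variable_sets()$automated
  pp <- fit_preprocessor(tab, feats)
  fit <- fit_logistic(apply_preprocessor(pp, tab), tab$outcome)
  expect_lt(unname(fit$coef["csf_ratio_24h"]), 0)
})

test_that("feed-forward network behaves at the limits and is seeded", {
  withr::with_seed(7, x <- matrix(rnorm(300), 100, 3))
  zero <- fit_fcnn(x, rep(0L, 100), model_spec("fcnn", seed = 3,
                                               max_epochs = 100))
  expect_true(all(predict_prob(zero, x) < 0.05))

  y <- as.integer(x[, 1] > 0)
  sep <- fit_fcnn(x, y, model_spec("fcnn", seed = 3, max_epochs = 200))
  expect_equal(roc_curve(y, predict_prob(sep, x))$auroc, 1,
               tolerance = 1e-6)
  sep2 <- fit_fcnn(x, y, model_spec("fcnn", seed = 3, max_epochs = 200))
  expect_identical(predict_prob(sep, x), predict_prob(sep2, x))
})

test_that("recurrent model learns a timestep-1 rule on held-out data", {
  withr::with_seed(8, {
    n <- 1200 ; d <- 4
    arr <- array(rnorm(n * 2 * d), c(n, 2, d))
    y <- as.integer(arr[, 2, 2] < -0.3)   # depends only on timestep 1
    tr <- 1:800 ; te <- 801:n
  })
  fit <- fit_lstm(arr[tr, , ], y[tr],
                  model_spec("lstm", hidden = 8, seed = 4,
                             max_epochs = 300, patience = 30))
  auc <- roc_curve(y[te], predict_prob(fit, arr[te, , ]))$auroc
  expect_gte(auc, 0.99)
  expect_error(fit_lstm(array(0, c(10, 3, 4)), rep(0:1, 5)), "two timesteps")
})

test_that("zero-initialised recurrence outputs sigmoid(bias) for any input", {
  par <- edemapredict:::lstm_init(3, 4)
  for (nm in c("Wx", "Wh", "Wo")) par[[nm]][] <- 0
  par$b[] <- 0 ; par$bo <- 0.7
  X <- matrix(rnorm(15), 5, 3)
  out <- edemapredict:::lstm_forward(par, X, X * 2)
  expect_equal(out$p, rep(plogis(0.7), 5), tolerance = 1e-12)
})

test_that("subject order does not affect seeded LSTM predictions", {
  withr::with_seed(9, {
    n <- 80 ; arr <- array(rnorm(n * 2 * 3), c(n, 2, 3))
    y <- rbinom(n, 1, 0.3) ; y[1:2] <- c(0, 1)
  })
  perm <- sample(n)
  # per-row stochastic elements (dropout masks, validation membership)
  # are disabled: what remains must be exactly order-invariant
  f1 <- fit_lstm(arr, y, model_spec("lstm", hidden = 4, seed = 5,
                                    max_epochs = 50, val_frac = 0,
                                    dropout = 0))
  f2 <- fit_lstm(arr[perm, , ], y[perm],
                 model_spec("lstm", hidden = 4, seed = 5,
                            max_epochs = 50, val_frac = 0, dropout = 0))
  p1 <- predict_prob(f1, arr)
  p2 <- predict_prob(f2, arr[perm, , ])[order(perm)]
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("nested CV predicts every subject exactly once out of fold", {
  tab <- small_cohort(n_total = 200, n_cases = 14)
  cv <- nested_cv(tab, model_spec("logistic"), variable_sets()$automated,
                  seed = 3)
  expect_equal(nrow(cv), nrow(tab))
  expect_false(anyNA(cv$prob))
  expect_true(all(cv$prob >= 0 & cv$prob <= 1))
  expect_identical(cv$id, tab$id)
  # bit-reproducible
  cv2 <- nested_cv(tab, model_spec("logistic"), variable_sets()$automated,
                   seed = 3)
  expect_identical(cv$prob, cv2$prob)
})

test_that("label-shuffled cohorts score near chance", {
  tab <- small_cohort(n_total = 300, n_cases = 20, seed = 77L)
  withr::with_seed(10, tab$outcome <- sample(tab$outcome))
  cv <- nested_cv(tab, model_spec("logistic"), variable_sets()$automated,
                  seed = 6)
  expect_lt(abs(roc_curve(cv$label, cv$prob)$auroc - 0.5), 0.12)
})

test_that("perturbing one subject cannot change same-fold neighbours'
           predictions (no leakage)", {
  tab <- small_cohort(n_total = 200, n_cases = 14, seed = 13L)
  cv <- nested_cv(tab, model_spec("logistic"), variable_sets()$automated,
                  seed = 8)
  sentinel <- which(cv$fold == 1)[1]
  tab2 <- tab
  tab2$glucose[sentinel] <- 5000
  tab2$csf_ratio_24h[sentinel] <- 9
  cv2 <- nested_cv(tab2, model_spec("logistic"), variable_sets()$automated,
                   seed = 8)
  same_fold_others <- setdiff(which(cv$fold == 1), sentinel)
  expect_identical(cv$prob[same_fold_others], cv2$prob[same_fold_others])
})

test_that("NIHSS subgroup filter keeps severe strokes and all thresholds", {
  tab <- generate_cohort(default_cohort_config(missingness_rate = 0,
                                               seed = 63L))
  sub <- subgroup_nihss(tab)
  expect_true(all(sub$nihss_baseline >= 8))
  frac <- nrow(sub) / nrow(tab)
  expect_gt(frac, 0.45) ; expect_lt(frac, 0.72)
  # essentially all cases retained (case median NIHSS far above 8)
  expect_gte(sum(sub$outcome == 1) / sum(tab$outcome == 1), 0.9)
  expect_identical(subgroup_nihss(tab, 0), tab)
  expect_error(subgroup_nihss(tab, 99), "empty")
})

test_that("sequence arrays follow the slot layout with zero baseline delta", {
  tab <- small_cohort()
  lay <- sequence_layout()
  pp <- fit_preprocessor(tab, lay$features)
  arr <- build_sequences(pp, tab, lay)
  expect_equal(dim(arr), c(nrow(tab), 2, length(lay$slots)))
  # static slots identical across timesteps
  for (s in c("age", "glucose", "tpa")) {
    expect_equal(arr[, 1, s], arr[, 2, s])
  }
  # t0 delta slot is the standardized image of raw zero
  p <- pp$pars$delta_csf
  expect_true(all(arr[, 1, "delta_csf"] == (0 - p$center) / p$scale))
  # t1 slots carry the 24-hour values
  m <- apply_preprocessor(pp, tab)
  expect_equal(arr[, 2, "nihss"], unname(m[, "nihss_24h"]))
})
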