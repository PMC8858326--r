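test_that("exact Shapley satisfies the axioms on random nonlinear models", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      d <- sample(3:5, 1)
      W <- matrix(rnorm(d * d, 0, 0.4), d)
      b <- rnorm(d)
      model_fn <- function(m) plogis(m %*% b + rowSums((m %*% W) * m) / d)
      inst <- rnorm(d)
      names(inst) <- paste0("x", 1:d)
      bg <- matrix(rnorm(4 * d), 4, d,
                   dimnames = list(NULL, names(inst)))
      at <- exact_shapley(model_fn, inst, bg)
      # efficiency
      expect_equal(at$base_value + sum(at$contributions),
                   unname(at$prediction), tolerance = 1e-10)
      expect_equal(unname(at$prediction), mean(model_fn(matrix(inst, 1)[rep(1, 1), , drop = FALSE])),
                   tolerance = 1e-10)
      # agreement with the permutation-average oracle
      expect_equal(unname(at$contributions),
                   perm_oracle(model_fn, inst, bg, d), tolerance = 1e-10)
    }
  })
})

test_that("dummy players get exactly zero contribution", {
  model_fn <- function(m) 2 * m[, 1] - m[, 3]  # ignores column 2
  inst <- c(a = 1, b = 5, c = 2)
  bg <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  at <- exact_shapley(model_fn, inst, bg)
  expect_equal(unname(at$contributions["b"]), 0)
})

test_that("symmetric players receive equal contributions", {
  model_fn <- function(m) m[, 1] + m[, 2]
  inst <- c(a = 3, b = 3)
  bg <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("a", "b")))
  at <- exact_shapley(model_fn, inst, bg)
  expect_equal(unname(at$contributions["a"]),
               unname(at$contributions["b"]))
})

test_that("linear models give the closed-form attribution", {
  w <- c(2, -1, 0.5, 3)
  model_fn <- function(m) drop(m %*% w) + 0.3
  inst <- c(p = 1, q = 2, r = -1, s = 0.5)
  z <- c(0.5, 0, 1, -2)
  bg <- matrix(z, 1, 4, dimnames = list(NULL, names(inst)))
  at <- exact_shapley(model_fn, inst, bg)
  expect_equal(unname(at$contributions), w * (unname(inst) - z),
               tolerance = 1e-8)
})

test_that("fused players mask all their columns jointly", {
  # columns 1 and 2 are two timestep slots of one variable
  model_fn <- function(m) m[, 1] + 10 * m[, 2] + m[, 3]
  inst <- c(v_t0 = 1, v_t1 = 2, w = 3)
  bg <- matrix(0, 1, 3, dimnames = list(NULL, names(inst)))
  at <- exact_shapley(model_fn, inst, bg,
                      players = list(v = c(1, 2), w = 3))
  expect_equal(unname(at$contributions["v"]), 1 + 10 * 2)
  expect_equal(unname(at$contributions["w"]), 3)
  # a model reading only timestep 0 still charges the fused player
  model_t0 <- function(m) 4 * m[, 1]
  at0 <- exact_shapley(model_t0, inst, bg,
                       players = list(v = c(1, 2), w = 3))
  expect_equal(unname(at0$contributions["v"]), 4)
  expect_equal(unname(at0$contributions["w"]), 0)
})

test_that("sampled estimator is unbiased and telescopes to efficiency", {
  withr::with_seed(31, {
    d <- 11
    w <- rnorm(d)
    model_fn <- function(m) plogis(m %*% w + 0.3 * m[, 1] * m[, 2])
    inst <- rnorm(d) ; names(inst) <- paste0("x", 1:d)
    bg <- matrix(rnorm(20 * d), 20, d, dimnames = list(NULL, names(inst)))
  })
  ex <- exact_shapley(model_fn, inst, bg)
  sa <- sampled_shapley(model_fn, inst, bg, permutations = 400, seed = 5)
  dev <- abs(ex$contributions - sa$contributions)
  expect_true(all(dev <= 3 * sa$mc_se + 1e-8))
  # one permutation still satisfies efficiency exactly
  one <- sampled_shapley(model_fn, inst, bg, permutations = 1, seed = 6)
  expect_equal(one$base_value + sum(one$contributions),
               mean(model_fn(matrix(inst, 1))), tolerance = 1e-10)
  # different seeds differ
  two <- sampled_shapley(model_fn, inst, bg, permutations = 5, seed = 7)
  expect_false(identical(sa$contributions, two$contributions))
})

test_that("player-count and degenerate-model guards fire", {
  inst <- stats::setNames(rnorm(17), paste0("x", 1:17))
  bg <- matrix(rnorm(17), 1, 17, dimnames = list(NULL, names(inst)))
  expect_error(exact_shapley(function(m) rowSums(m), inst, bg),
               "sampled_shapley")
  inst3 <- c(a = 1, b = 2)
  bg3 <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(exact_shapley(function(m) rep(NaN, nrow(m)), inst3, bg3),
               "non-finite")
})

test_that("global summaries rank by mean absolute contribution", {
  mk <- function(contrib) structure(list(base_value = 0.4,
                                         contributions = contrib,
                                         prediction = 0.4 + sum(contrib)),
                                    class = "attribution")
  atts <- list(mk(c(a = 0.3, b = -0.1, c = 0)),
               mk(c(a = -0.2, b = 0.3, c = 0)))
  gs <- global_summary(atts)
  expect_equal(gs$ranking[1], "a")  # mean |a| = .25 > mean |b| = .20
  expect_equal(unname(gs$importance["c"]), 0)
  # constant model: all zeros
  gz <- global_summary(list(mk(c(a = 0, b = 0, c = 0))))
  expect_true(all(gz$importance == 0))
  bad <- list(mk(c(a = 1, b = 2, c = 3)), mk(c(x = 1, y = 2, z = 3)))
  expect_error(global_summary(bad), "inconsistent")
})

test_that("force reports run cumulatively from base to final prediction", {
  at <- structure(list(base_value = 0.46,
                       contributions = c(csf_ratio_24h = 0.30,
                                         nihss_24h = 0.15,
                                         age = -0.03),
                       prediction = 0.88),
                  class = "attribution")
  fr <- force_report(at, c(csf_ratio_24h = 0.2, nihss_24h = 22, age = 60))
  expect_equal(fr$base_value, 0.46)
  expect_equal(fr$final, 0.88)
  expect_equal(fr$steps$cumulative[nrow(fr$steps)], 0.88)
  expect_equal(fr$steps$player[1], "csf_ratio_24h")  # largest |contribution|
  zero <- structure(list(base_value = 0.5,
                         contributions = c(a = 0, b = 0),
                         prediction = 0.5), class = "attribution")
  frz <- force_report(zero)
  expect_equal(frz$final, frz$base_value)
})
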