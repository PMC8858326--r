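test_that("default cohort has the designed size, prevalence and ids", {
  tab <- generate_cohort(default_cohort_config(missingness_rate = 0,
                                               seed = 3L))
  expect_equal(nrow(tab), 598L)
  expect_equal(sum(tab$outcome == 1L), 20L)
  expect_false(anyDuplicated(tab$id) > 0)
  expect_true(all(tab$nihss_baseline >= 0 & tab$nihss_baseline <= 42))
  expect_true(all(tab$nihss_24h >= 0 & tab$nihss_24h <= 42))
  expect_true(all(tab$aspects >= 0 & tab$aspects <= 10))
  expect_true(all(tab$intracranial_reserve > 0 &
                    tab$intracranial_reserve < 1))
  expect_true(all(tab$csf_ratio_24h >= 0))
  expect_true(all(tab$delta_csf >= -100))
  expect_true(all(tab$midline_shift_24h >= 0))
})

test_that("cohorts are deterministic per seed and differ across seeds", {
  a <- generate_cohort(default_cohort_config(seed = 11L))
  b <- generate_cohort(default_cohort_config(seed = 11L))
  c <- generate_cohort(default_cohort_config(seed = 12L))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a)$age, as.data.frame(c)$age))
})

test_that("invalid configurations are rejected", {
  expect_error(default_cohort_config(n_total = 10, n_cases = 10),
               "n_cases")
  expect_error(default_cohort_config(missingness_rate = 1), "missingness")
  cfg <- default_cohort_config()
  cfg$copula$case["age", "glucose"] <- 0.99
  expect_error(validate_cohort_config(cfg), "symmetric")
  cfg <- default_cohort_config()
  cfg$copula$control["age", "glucose"] <-
    cfg$copula$control["glucose", "age"] <- 0.99
  cfg$copula$control["age", "sbp"] <-
    cfg$copula$control["sbp", "age"] <- 0.99
  cfg$copula$control["glucose", "sbp"] <-
    cfg$copula$control["sbp", "glucose"] <- -0.99
  expect_error(validate_cohort_config(cfg), "positive semi-definite")
})

test_that("missingness injection is MCAR at the requested rate and seeded", {
  tab <- generate_cohort(default_cohort_config(missingness_rate = 0,
                                               seed = 5L))
  expect_false(anyNA(tab))
  m1 <- inject_missingness(tab, 0.05, seed = 9L)
  m2 <- inject_missingness(tab, 0.05, seed = 9L)
  expect_identical(m1, m2)
  feature_cols <- setdiff(names(tab), c("id", "outcome"))
  frac <- mean(is.na(as.matrix(m1[feature_cols])))
  n_cells <- nrow(tab) * length(feature_cols)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_cells))
  expect_false(anyNA(m1$outcome))
  expect_false(anyNA(m1$id))
  expect_identical(inject_missingness(tab, 0), tab)
  expect_error(inject_missingness(tab, 1.2), "rate")
})

test_that("group summaries recover configured locations at moderate n", {
  cfg <- default_cohort_config(n_total = 8000L, n_cases = 4000L,
                               missingness_rate = 0, seed = 21L)
  s <- summarize_cohort(generate_cohort(cfg))
  g <- s$groups
  get <- function(grp, feat, stat) g[g$group == grp & g$feature == feat, stat]
  # mean-reported features: within ~3 MC SE of Table-style locations
  expect_lt(abs(get("case", "glucose", "mean") - 202), 3 * 109 / sqrt(4000) + 2)
  expect_lt(abs(get("control", "sbp", "mean") - 160), 3 * 28 / sqrt(4000) + 1)
  expect_lt(abs(get("case", "delta_csf", "mean") + 52), 3 * 18 / sqrt(4000) + 0.3)
  # median-reported features recover the printed medians
  expect_lt(abs(get("case", "csf_ratio_24h", "median") - 0.26), 0.02)
  expect_lt(abs(get("control", "csf_ratio_24h", "median") - 0.90), 0.02)
  expect_lt(abs(get("control", "nihss_baseline", "median") - 9), 1)
  expect_lt(abs(get("case", "nihss_baseline", "median") - 18.5), 1)
})

test_that("summaries handle degenerate groups", {
  tab <- small_cohort(n_total = 30, n_cases = 10)
  one_case <- tab[c(which(tab$outcome == 1)[1], which(tab$outcome == 0)), ]
  s <- summarize_cohort(one_case)
  row <- s$groups[s$groups$group == "case" & s$groups$feature == "age", ]
  expect_true(is.na(row$sd))
  expect_equal(row$median, one_case$age[one_case$outcome == 1])
  dup <- tab[rep(which(tab$outcome == 1)[1], 2), ]
  dup <- rbind(dup, tab[tab$outcome == 0, ])
  s2 <- summarize_cohort(dup)
  expect_equal(s2$groups[s2$groups$group == "case" &
                           s2$groups$feature == "age", "iqr"], 0)
  only_ctrl <- tab[tab$outcome == 0, ]
  expect_error(summarize_cohort(only_ctrl), "both outcome groups")
})

test_that("high-risk quadrant rule uses strict inequalities", {
  expect_true(flag_high_risk_quadrant(-52, 0.26))
  expect_false(flag_high_risk_quadrant(-20, 0.26))
  expect_false(flag_high_risk_quadrant(-52, 0.60))
  expect_error(flag_high_risk_quadrant(NA, 0.3), "non-missing")
  expect_equal(flag_high_risk_quadrant(c(-52, -10), c(0.2, 0.2)),
               c(TRUE, FALSE))
})

test_that("nearly all simulated cases fall in the high-risk quadrant", {
  cfg <- default_cohort_config(n_total = 5200L, n_cases = 5000L,
                               missingness_rate = 0, seed = 31L)
  tab <- generate_cohort(cfg)
  case <- tab[tab$outcome == 1L, ]
  frac <- mean(flag_high_risk_quadrant(case$delta_csf, case$csf_ratio_24h))
  expect_gt(frac, 0.93)
})

test_that("cohort CSV round-trips with empty-field missing values", {
  tab <- small_cohort(missingness = 0.05)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort_csv(tab, path)
  expect_true(file.exists(paste0(path, ".provenance.json")))
  back <- read_cohort_csv(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(sum(is.na(back$glucose)), sum(is.na(tab$glucose)))
  expect_equal(back$age, tab$age, tolerance = 1e-12)
})
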