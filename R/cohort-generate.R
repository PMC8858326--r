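# Synthetic cohort generation --------------------------------------------

#' Generate a synthetic stroke cohort
#'
#' Draws `n_total` patient records, exactly `n_cases` of which carry the
#' malignant-edema outcome (stratified assignment, not Bernoulli draws).
#' Within each outcome group, continuous and score features are coupled
#' through a Gaussian copula with the configured latent correlation matrix;
#' marginals follow the configured families. The 24-hour NIHSS is derived as
#' baseline + group-specific change clamped to `[0, 42]`; `delta_csf` is
#' signed (negative = CSF displaced by edema). Missingness (MCAR at
#' `missingness_rate`) is applied to every feature cell except id and
#' outcome. Deterministic for a fixed seed.
#'
#' @param config a [default_cohort_config()]-style `cohort_config`.
#' @param seed integer; overrides `config$seed` when given.
#' @return A `cohort_table`: a `data.frame` with one row per patient and
#'   columns id, outcome, age, nihss_baseline, nihss_24h, glucose, sbp, tpa,
#'   aspects, intracranial_reserve, csf_ratio_baseline, csf_ratio_24h,
#'   delta_csf, midline_shift_24h, infarct_volume_24h; provenance (config,
#'   seed) stored in attributes.
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  seed <- as.integer(seed %||% config$seed)
  n_cases <- config$n_cases
  n_controls <- config$n_total - n_cases

  withr::with_seed(seed, {
    cases <- draw_group(config, "case", n_cases)
    controls <- draw_group(config, "control", n_controls)
    tab <- rbind(cbind(outcome = 1L, cases), cbind(outcome = 0L, controls))
    # shuffle rows so cases are interspersed as in a real registry export
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    tab <- cbind(id = sprintf("S%04d", seq_len(nrow(tab))), tab)
    rownames(tab) <- NULL
    tab <- structure(tab, class = c("cohort_table", "data.frame"),
                     config = config, seed = seed)
    if (config$missingness_rate > 0) {
      tab <- inject_missingness(tab, config$missingness_rate,
                                seed = derive_seed(seed, "missingness"))
    }
    tab
  })
}

# Draw n records for one outcome group ("case"/"control").
draw_group <- function(config, group, n) {
  cm <- config$copula[[group]]
  d <- ncol(cm)
  z <- matrix(stats::rnorm(n * d), n, d) %*% chol(cm)
  u <- stats::pnorm(z)
  colnames(u) <- colnames(cm)

  col <- function(nm) {
    f <- config$features[[nm]][[group]]
    marginal_from_uniform(u[, nm], f)
  }
  age <- col("age")
  nihss_baseline <- col("nihss_baseline")
  nihss_change <- col("nihss_change")
  nihss_24h <- as.integer(clamp(round(nihss_baseline + nihss_change), 0, 42))
  glucose <- col("glucose")
  sbp <- col("sbp")
  aspects <- col("aspects")
  reserve <- col("intracranial_reserve")
  ratio_base <- col("csf_ratio_baseline")
  ratio_24 <- col("csf_ratio_24h")
  delta <- col("delta_csf")

  ftpa <- config$features$tpa[[group]]
  tpa <- as.integer(stats::runif(n) < ftpa$p)

  shift <- draw_zilognorm(config$features$midline_shift_24h[[group]], n)
  infarct <- draw_zilognorm(config$features$infarct_volume_24h[[group]], n)

  data.frame(
    age = age, nihss_baseline = as.integer(nihss_baseline),
    nihss_24h = nihss_24h, glucose = glucose, sbp = sbp, tpa = tpa,
    aspects = as.integer(aspects), intracranial_reserve = reserve,
    csf_ratio_baseline = ratio_base, csf_ratio_24h = ratio_24,
    delta_csf = delta, midline_shift_24h = shift,
    infarct_volume_24h = infarct
  )
}

marginal_from_uniform <- function(u, f) {
  switch(f$family,
    truncnorm = qtrunc_norm(u, f$latent_location %||% f$location, f$scale,
                            f$lo %||% -Inf, f$hi %||% Inf),
    normal = stats::qnorm(u, f$location, f$scale),
    intclampnorm = round(clamp(stats::qnorm(u, f$location, f$scale),
                               f$lo, f$hi)),
    stop_config("unknown marginal family '%s'", f$family)
  )
}

# Zero-inflated lognormal with an exact (rounded) zero count, so that the
# published "three of twenty cases had no shift"-style overlaps are met
# exactly at the default group sizes.
draw_zilognorm <- function(f, n) {
  n_zero <- round(f$p_zero * n)
  x <- stats::rlnorm(n, f$meanlog, f$sdlog)
  x[sample.int(n, n_zero)] <- 0
  x
}

#' Mask feature cells completely at random
#'
#' Each non-id, non-outcome cell is independently set to `NA` with
#' probability `rate`; outcome and id are never masked. Identical seeds give
#' identical masks.
#'
#' @param table a `cohort_table`.
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The masked `cohort_table`.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop_config("missingness rate must be in [0, 1)")
  if (rate == 0) return(table)
  feature_cols <- setdiff(names(table), c("id", "outcome"))
  withr::with_seed(as.integer(seed), {
    for (nm in feature_cols) {
      mask <- stats::runif(nrow(table)) < rate
      table[[nm]][mask] <- NA
    }
  })
  table
}

#' Per-group summaries and pooled correlations for a cohort
#'
#' Computes per-outcome-group mean/SD and median/IQR for every numeric
#' feature, plus pooled Pearson correlations among the 24-hour CSF ratio,
#' signed percent CSF change, and 24-hour NIHSS — the quantities used to
#' check calibration against the published group statistics.
#'
#' @param table a `cohort_table` with both outcome groups present.
#' @return A list with elements `groups` (a long `data.frame` with columns
#'   group, feature, mean, sd, median, iqr, n) and `correlations` (named
#'   vector with `ratio24_delta`, `ratio24_nihss24`, `delta_nihss24`).
#' @export
summarize_cohort <- function(table) {
  if (!all(c(0L, 1L) %in% table$outcome))
    stop_config("both outcome groups must be present")
  feature_cols <- setdiff(names(table), c("id", "outcome"))
  rows <- list()
  for (grp in c(1L, 0L)) {
    sub <- table[table$outcome == grp, , drop = FALSE]
    for (nm in feature_cols) {
      x <- sub[[nm]][!is.na(sub[[nm]])]
      rows[[length(rows) + 1L]] <- data.frame(
        group = if (grp == 1L) "case" else "control",
        feature = nm,
        mean = mean(x),
        sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
        median = stats::median(x),
        iqr = stats::IQR(x),
        n = length(x)
      )
    }
  }
  cc <- function(a, b) {
    ok <- stats::complete.cases(table[[a]], table[[b]])
    stats::cor(table[[a]][ok], table[[b]][ok])
  }
  list(
    groups = do.call(rbind, rows),
    correlations = c(
      ratio24_delta = cc("csf_ratio_24h", "delta_csf"),
      ratio24_nihss24 = cc("csf_ratio_24h", "nihss_24h"),
      delta_nihss24 = cc("delta_csf", "nihss_24h")
    )
  )
}

#' High-risk quadrant flag
#'
#' A subject lies in the high-risk quadrant when the signed percent CSF
#' change is below -20% and the 24-hour hemispheric CSF ratio is below 0.60
#' (strict inequalities) — the region of feature space where all malignant
#' edema cases were observed.
#'
#' @param delta_csf signed percent CSF change (vectorised).
#' @param csf_ratio_24h 24-hour hemispheric CSF ratio (vectorised).
#' @return Logical vector.
#' @export
flag_high_risk_quadrant <- function(delta_csf, csf_ratio_24h) {
  if (any(is.na(delta_csf)) || any(is.na(csf_ratio_24h)))
    stop_config("delta_csf and csf_ratio_24h must be non-missing")
  delta_csf < -20 & csf_ratio_24h < 0.60
}

#' Write / read a cohort as CSV with a provenance sidecar
#'
#' Missing values are written as empty fields; a `<path>.provenance.json`
#' sidecar records the generating seed and config checksum.
#'
#' @param table a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  out <- as.data.frame(table)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      # full precision so a written cohort reproduces results bit-for-bit
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  prov <- list(
    seed = attr(table, "seed"),
    n_total = nrow(table),
    n_cases = sum(table$outcome == 1L, na.rm = TRUE)
  )
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(tab, class = c("cohort_table", "data.frame"))
}
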