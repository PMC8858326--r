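# Feature sets, preprocessing, nested stratified cross-validation --------

#' Predictor variable sets
#'
#' The five preset feature sets used by the prediction models:
#' 1. `baseline`: baseline-only clinical + imaging variables;
#' 2. `baseline_delta`: + 24-hour NIHSS and percent CSF change;
#' 3. `automated`: + 24-hour hemispheric CSF ratio (all 11 automated
#'    variables);
#' 4. `all`: + manually measured midline shift and infarct volume;
#' 5. `lstm_automated`: the automated set arranged as two timesteps
#'    (see [sequence_layout()]).
#'
#' @return Named list of character vectors (for set 5, the layout object).
#' @export
variable_sets <- function() {
  base <- c("age", "nihss_baseline", "glucose", "sbp", "tpa", "aspects",
            "intracranial_reserve", "csf_ratio_baseline")
  list(
    baseline = base,
    baseline_delta = c(base, "nihss_24h", "delta_csf"),
    automated = c(base, "nihss_24h", "delta_csf", "csf_ratio_24h"),
    all = c(base, "nihss_24h", "delta_csf", "csf_ratio_24h",
            "midline_shift_24h", "infarct_volume_24h"),
    lstm_automated = sequence_layout()
  )
}

#' Two-timestep slot layout for the recurrent model
#'
#' Both timesteps share one 9-slot layout: six static slots (age, glucose,
#' SBP, tPA, ASPECTS, intracranial reserve) repeated at both timesteps, and
#' three time-varying slots holding NIHSS, hemispheric CSF ratio and percent
#' CSF change at the respective timepoint. At baseline the CSF change slot
#' is identically zero (no change has occurred yet).
#'
#' @return A list of class `sequence_layout` with `slots`, `t0`, `t1`
#'   (source column per slot; `".zero"` denotes the constant 0) and
#'   `features` (the union of source columns).
#' @export
sequence_layout <- function() {
  static <- c("age", "glucose", "sbp", "tpa", "aspects",
              "intracranial_reserve")
  slots <- c(static, "nihss", "csf_ratio", "delta_csf")
  t0 <- c(static, "nihss_baseline", "csf_ratio_baseline", ".zero")
  t1 <- c(static, "nihss_24h", "csf_ratio_24h", "delta_csf")
  structure(list(slots = slots, t0 = t0, t1 = t1,
                 features = unique(c(t0[t0 != ".zero"], t1))),
            class = "sequence_layout")
}

is_sequence_set <- function(vs) inherits(vs, "sequence_layout")

#' Fit / apply the per-fold preprocessor
#'
#' Estimates per-feature median imputation values and z-score parameters on
#' training rows only; binary features (values in \{0,1\}) are imputed but
#' passed through unscaled; zero-variance features get unit scale (their
#' standardized column is constant zero). Applying the transform never
#' re-estimates anything, so test rows cannot leak into it.
#'
#' @param train a `cohort_table` (or data.frame) of training rows.
#' @param features character vector of feature columns.
#' @return An object of class `preprocessor`.
#' @export
fit_preprocessor <- function(train, features) {
  if (length(unique(train$outcome)) < 2)
    stop_config("training rows must contain both classes")
  pars <- lapply(features, function(nm) {
    x <- train[[nm]]
    if (is.null(x)) stop_config("feature '%s' absent from table", nm)
    obs <- x[!is.na(x)]
    if (length(obs) == 0L)
      stop_config("feature '%s' entirely missing in training rows", nm)
    binary <- all(obs %in% c(0, 1))
    med <- stats::median(obs)
    xi <- ifelse(is.na(x), med, x)
    s <- stats::sd(xi)
    list(median = med, center = if (binary) 0 else mean(xi),
         scale = if (binary || !is.finite(s) || s == 0) 1 else s,
         binary = binary)
  })
  names(pars) <- features
  structure(list(features = features, pars = pars), class = "preprocessor")
}

#' @rdname fit_preprocessor
#' @param pp a fitted `preprocessor`.
#' @param rows rows to transform.
#' @return `apply_preprocessor` returns a numeric matrix with one
#'   standardized column per feature.
#' @export
apply_preprocessor <- function(pp, rows) {
  stopifnot(inherits(pp, "preprocessor"))
  out <- vapply(pp$features, function(nm) {
    p <- pp$pars[[nm]]
    x <- rows[[nm]]
    x <- ifelse(is.na(x), p$median, x)
    (x - p$center) / p$scale
  }, numeric(nrow(rows)))
  matrix(out, nrow = nrow(rows),
         dimnames = list(NULL, pp$features))
}

#' Build the two-timestep sequence array
#'
#' Arranges preprocessed features into the `n x 2 x d` array consumed by
#' [fit_lstm()], following [sequence_layout()]. The preprocessor must have
#' been fitted on the layout's feature union; the baseline CSF-change slot
#' holds the standardized image of a raw 0.
#'
#' @param pp a `preprocessor` fitted on `layout$features`.
#' @param rows rows to transform.
#' @param layout a [sequence_layout()].
#' @return Numeric array `n x 2 x length(layout$slots)`.
#' @export
build_sequences <- function(pp, rows, layout = sequence_layout()) {
  m <- apply_preprocessor(pp, rows)
  n <- nrow(m)
  d <- length(layout$slots)
  arr <- array(0, c(n, 2, d),
               dimnames = list(NULL, c("t0", "t1"), layout$slots))
  fill <- function(tstep, sources) {
    for (s in seq_len(d)) {
      src <- sources[s]
      if (src == ".zero") {
        p <- pp$pars[["delta_csf"]]
        arr[, tstep, s] <<- (0 - p$center) / p$scale
      } else {
        arr[, tstep, s] <<- m[, src]
      }
    }
  }
  fill(1, layout$t0)
  fill(2, layout$t1)
  arr
}

#' Stratified cross-validation plan
#'
#' Partitions subjects into `k` outer folds with cases and controls each
#' split as evenly as counts allow (dealt round-robin after a seeded
#' shuffle). With 20 cases in 10 folds every test fold holds exactly 2
#' cases.
#'
#' @param outcome binary outcome vector.
#' @param k number of outer folds.
#' @param seed shuffle seed.
#' @return Integer vector of fold assignments (1..k), one per subject.
#' @export
make_cv_plan <- function(outcome, k = 10L, seed = 1L) {
  if (length(unique(outcome)) < 2) stop_config("both classes required")
  n1 <- sum(outcome == 1)
  if (n1 < k)
    stop_config("fewer cases (%d) than folds (%d): use k <= %d", n1, k, n1)
  fold <- integer(length(outcome))
  withr::with_seed(as.integer(seed), {
    for (cls in c(1, 0)) {
      idx <- sample(which(outcome == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Nested stratified cross-validation
#'
#' For each outer fold: an inner stratified cross-validation over the
#' hyperparameter grid selects the configuration with the highest inner
#' out-of-fold AUPRC; preprocessor and model are then refitted on the whole
#' outer-training set and predictions emitted for the outer-test set only.
#' Imputation, standardization and selection therefore never see outer-test
#' rows.
#'
#' @param table a `cohort_table` with an `outcome` column.
#' @param spec a [model_spec()]; `spec$grid` (or the default grid for the
#'   kind) is searched in the inner loop.
#' @param variable_set a character vector of features, or a
#'   [sequence_layout()] for the recurrent model.
#' @param k_outer,k_inner fold counts.
#' @param seed plan seed (outer and inner splits derive from it).
#' @return A `cv_result`: data.frame (id, fold, label, prob) with the
#'   chosen per-fold hyperparameters in `attr(, "chosen")`.
#' @export
nested_cv <- function(table, spec, variable_set, k_outer = 10L,
                      k_inner = 5L, seed = 1L) {
  y <- table$outcome
  fold <- make_cv_plan(y, k_outer, seed = seed)
  grid <- spec$grid %||% default_grid(spec$kind)
  prob <- rep(NA_real_, nrow(table))
  chosen <- vector("list", k_outer)

  for (f in seq_len(k_outer)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    tr <- table[tr_idx, , drop = FALSE]

    if (length(grid) == 1L) {
      # a single configuration needs no inner selection
      chosen[[f]] <- grid[[1L]]
      fitted <- fit_one(tr, merge_spec(spec, grid[[1L]]), variable_set)
      prob[te_idx] <- predict_one(fitted, table[te_idx, , drop = FALSE],
                                  variable_set)
      next
    }

    inner_fold <- make_cv_plan(tr$outcome, k_inner,
                               seed = derive_seed(seed, paste0("inner", f)))
    scores <- vapply(seq_along(grid), function(gi) {
      sp <- merge_spec(spec, grid[[gi]])
      ip <- rep(NA_real_, nrow(tr))
      for (g in seq_len(k_inner)) {
        it <- which(inner_fold != g)
        iv <- which(inner_fold == g)
        fitted <- fit_one(tr[it, , drop = FALSE], sp, variable_set)
        ip[iv] <- predict_one(fitted, tr[iv, , drop = FALSE], variable_set)
      }
      pr_curve(tr$outcome, ip)$auprc
    }, numeric(1))
    best <- which.max(scores)
    sp <- merge_spec(spec, grid[[best]])
    chosen[[f]] <- c(grid[[best]], inner_auprc = scores[best])

    fitted <- fit_one(tr, sp, variable_set)
    prob[te_idx] <- predict_one(fitted, table[te_idx, , drop = FALSE],
                                variable_set)
  }

  structure(data.frame(id = table$id, fold = fold, label = y, prob = prob,
                       stringsAsFactors = FALSE),
            chosen = chosen, kind = spec$kind, seed = seed,
            class = c("cv_result", "data.frame"))
}

merge_spec <- function(spec, over) {
  for (nm in setdiff(names(over), "inner_auprc")) spec[[nm]] <- over[[nm]]
  spec
}

# fit preprocessor + model on a training table; returns both
fit_one <- function(train, spec, variable_set) {
  if (is_sequence_set(variable_set)) {
    pp <- fit_preprocessor(train, variable_set$features)
    xs <- build_sequences(pp, train, variable_set)
    model <- fit_lstm(xs, train$outcome, spec)
  } else {
    pp <- fit_preprocessor(train, variable_set)
    x <- apply_preprocessor(pp, train)
    model <- switch(spec$kind,
      logistic = fit_logistic(x, train$outcome, spec),
      fcnn = fit_fcnn(x, train$outcome, spec),
      lstm = stop_config("lstm requires a sequence_layout variable set"))
  }
  list(pp = pp, model = model)
}

predict_one <- function(fitted, rows, variable_set) {
  if (is_sequence_set(variable_set)) {
    predict_prob(fitted$model, build_sequences(fitted$pp, rows, variable_set))
  } else {
    predict_prob(fitted$model, apply_preprocessor(fitted$pp, rows))
  }
}

#' Restrict a cohort to the moderate-to-severe subgroup
#'
#' Filters to subjects with baseline NIHSS at or above the threshold
#' (default 8), the sensitivity-analysis subgroup.
#'
#' @param table a `cohort_table`.
#' @param threshold minimum baseline NIHSS retained.
#' @return The filtered `cohort_table` (records unchanged).
#' @export
subgroup_nihss <- function(table, threshold = 8) {
  out <- table[!is.na(table$nihss_baseline) &
                 table$nihss_baseline >= threshold, , drop = FALSE]
  if (nrow(out) == 0L) stop_config("subgroup is empty")
  out
}
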