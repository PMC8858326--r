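# Exact and sampled Shapley-value attribution ----------------------------

#' Exact Shapley attribution for one prediction
#'
#' Computes interventional Shapley values on the probability scale by full
#' coalition enumeration. For a coalition S, the value v(S) is the mean
#' model output over the background set with the features in S taken from
#' the explained instance and the rest from the background row. The base
#' value is v(empty) — the mean prediction when no features are known — and
#' by the efficiency axiom base + sum(contributions) equals the model's
#' prediction for the instance.
#'
#' A player is a named variable; `players` may map one player to several
#' columns (e.g. the baseline and 24-hour slots of one variable in a
#' recurrent model are masked jointly).
#'
#' @param model_fn function taking a numeric matrix (rows = feature
#'   vectors) and returning a probability per row.
#' @param instance named numeric vector: the prediction to explain.
#' @param background matrix/data.frame of background rows (same columns).
#' @param players optional named list mapping player names to column
#'   indices/names; defaults to one player per column.
#' @return An `attribution`: list with `base_value`, `contributions`
#'   (named), `prediction`, `players`.
#' @export
exact_shapley <- function(model_fn, instance, background, players = NULL) {
  bg <- as.matrix(background)
  if (nrow(bg) == 0L) stop_config("background set must be non-empty")
  players <- normalize_players(players, instance)
  d <- length(players)
  if (d > 16L)
    stop_config("%d players would need 2^%d coalitions; use sampled_shapley()",
                d, d)
  n_mask <- bitwShiftL(1L, d)

  v <- numeric(n_mask)
  chunk <- max(1L, 65536L %/% nrow(bg))
  x_inst <- as.numeric(instance)
  for (start in seq(0L, n_mask - 1L, by = chunk)) {
    masks <- start:min(start + chunk - 1L, n_mask - 1L)
    rows <- matrix(rep(t(bg), length(masks)), ncol = ncol(bg), byrow = TRUE)
    for (mi in seq_along(masks)) {
      m <- masks[mi]
      cols <- unlist(players[bitwAnd(bitwShiftL(1L, seq_len(d) - 1L), m) != 0L],
                     use.names = FALSE)
      if (length(cols)) {
        rr <- (mi - 1L) * nrow(bg) + seq_len(nrow(bg))
        rows[rr, cols] <- matrix(x_inst[cols], length(rr), length(cols),
                                 byrow = TRUE)
      }
    }
    out <- model_fn(rows)
    if (!all(is.finite(out))) stop_config("model_fn returned non-finite output")
    v[masks + 1L] <- colMeans(matrix(out, nrow = nrow(bg)))
  }

  pop <- popcount(0:(n_mask - 1L))
  wgt <- factorial(0:(d - 1)) * factorial(d - 1 - 0:(d - 1)) / factorial(d)
  phi <- numeric(d)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_mask - 1L), bit) == 0L)
    phi[j] <- sum(wgt[pop[without] + 1L] *
                    (v[without + bit] - v[without]))
  }
  names(phi) <- names(players)
  structure(list(base_value = v[1L], contributions = phi,
                 prediction = v[n_mask], players = players),
            class = "attribution")
}

popcount <- function(x) {
  out <- integer(length(x))
  while (any(x > 0L)) {
    out <- out + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  out
}

normalize_players <- function(players, instance) {
  if (is.null(players)) {
    nm <- names(instance) %||% paste0("x", seq_along(instance))
    players <- as.list(stats::setNames(seq_along(instance), nm))
  }
  lapply(players, function(p) {
    if (is.character(p)) match(p, names(instance)) else as.integer(p)
  })
}

#' Monte-Carlo permutation estimate of Shapley values
#'
#' Unbiased estimator of the exact values: for each sampled permutation,
#' players are revealed in order and their marginal value contributions
#' accumulated. Each marginal is a paired difference along the same
#' permutation walk, so the estimate telescopes to the exact efficiency
#' identity for every sample size.
#'
#' @inheritParams exact_shapley
#' @param permutations number of sampled permutations (>= 1).
#' @param seed sampling seed.
#' @return An `attribution` (with Monte-Carlo standard errors in `mc_se`).
#' @export
sampled_shapley <- function(model_fn, instance, background, players = NULL,
                            permutations = 200L, seed = 1L) {
  if (permutations < 1) stop_config("permutations must be >= 1")
  bg <- as.matrix(background)
  if (nrow(bg) == 0L) stop_config("background set must be non-empty")
  players <- normalize_players(players, instance)
  d <- length(players)
  x_inst <- as.numeric(instance)

  coalition_value <- function(active) {
    rows <- bg
    cols <- unlist(players[active], use.names = FALSE)
    if (length(cols))
      rows[, cols] <- matrix(x_inst[cols], nrow(bg), length(cols),
                             byrow = TRUE)
    out <- model_fn(rows)
    if (!all(is.finite(out))) stop_config("model_fn returned non-finite output")
    mean(out)
  }

  contrib <- matrix(0, permutations, d)
  base <- coalition_value(logical(d))
  withr::with_seed(as.integer(seed), {
    for (s in seq_len(permutations)) {
      ord <- sample.int(d)
      active <- logical(d)
      prev <- base
      for (j in ord) {
        active[j] <- TRUE
        cur <- coalition_value(active)
        contrib[s, j] <- cur - prev
        prev <- cur
      }
    }
  })
  phi <- colMeans(contrib)
  names(phi) <- names(players)
  mc_se <- apply(contrib, 2, stats::sd) / sqrt(permutations)
  structure(list(base_value = base, contributions = phi,
                 prediction = base + sum(phi), players = players,
                 mc_se = stats::setNames(mc_se, names(players))),
            class = "attribution")
}

#' Global attribution summary across a cohort
#'
#' Ranks players by mean absolute contribution and collects the
#' (feature value, contribution) pairs that drive beeswarm-style summary
#' plots.
#'
#' @param attributions list of `attribution` objects with identical player
#'   sets.
#' @param values optional data.frame of raw feature values (one row per
#'   attribution) for the value-vs-effect pairs.
#' @return A `global_summary`: list with `importance` (named, sorted
#'   descending), `ranking`, and `pairs`.
#' @export
global_summary <- function(attributions, values = NULL) {
  if (length(attributions) == 0L) stop_config("need at least one attribution")
  nm <- names(attributions[[1]]$contributions)
  mat <- t(vapply(attributions, function(a) {
    if (!identical(names(a$contributions), nm))
      stop_config("attributions have inconsistent player sets")
    a$contributions
  }, numeric(length(nm))))
  importance <- sort(colMeans(abs(mat)), decreasing = TRUE)
  pairs <- NULL
  if (!is.null(values)) {
    pairs <- do.call(rbind, lapply(nm, function(p) {
      data.frame(player = p, value = values[[p]], contribution = mat[, p])
    }))
  }
  structure(list(importance = importance, ranking = names(importance),
                 contributions = mat, pairs = pairs),
            class = "global_summary")
}

#' Force-style report for one attribution
#'
#' Features sorted by absolute contribution with sign, raw value, and the
#' running cumulative prediction from the base value to the final model
#' output; serialises cleanly to JSON.
#'
#' @param attribution an `attribution`.
#' @param feature_values optional named vector of raw feature values.
#' @return A `force_report`: list with `base_value`, `final`, and `steps`
#'   (a data.frame player/value/contribution/cumulative).
#' @export
force_report <- function(attribution, feature_values = NULL) {
  phi <- attribution$contributions
  ord <- order(abs(phi), decreasing = TRUE)
  cum <- attribution$base_value + cumsum(phi[ord])
  steps <- data.frame(
    player = names(phi)[ord],
    value = if (is.null(feature_values)) NA_real_ else
      as.numeric(feature_values[names(phi)[ord]]),
    contribution = as.numeric(phi[ord]),
    direction = ifelse(phi[ord] >= 0, "higher-risk", "lower-risk"),
    cumulative = as.numeric(cum)
  )
  structure(list(base_value = attribution$base_value,
                 final = unname(cum[length(cum)]),
                 steps = steps),
            class = "force_report")
}

#' Model function over raw cohort rows for a fitted pipeline
#'
#' Wraps a fitted preprocessor + model pair (as produced inside
#' [nested_cv()] or [run_pipeline()]) as a plain matrix-to-probability
#' function over the raw feature columns, for use with [exact_shapley()].
#' For the recurrent model each clinical variable enters as one player:
#' masking it swaps the raw value, which changes every timestep slot it
#' feeds jointly.
#'
#' @param fitted list with elements `pp` and `model`.
#' @param variable_set character feature set or [sequence_layout()].
#' @param feature_cols the raw columns of the matrix rows (defaults to the
#'   variable set's features).
#' @return A function `matrix -> probabilities`.
#' @export
shapley_model_fn <- function(fitted, variable_set,
                             feature_cols = NULL) {
  cols <- feature_cols %||% (if (is_sequence_set(variable_set))
    variable_set$features else variable_set)
  function(m) {
    df <- as.data.frame(m)
    names(df) <- cols
    predict_one(fitted, df, variable_set)
  }
}
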