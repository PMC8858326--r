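# Shared fixtures, built in code at test time.

# small cohort for fast model tests (still >= 10 cases so 10-fold CV works)
small_cohort <- function(n_total = 180L, n_cases = 12L, seed = 42L,
                         missingness = 0) {
  cfg <- default_cohort_config(n_total = n_total, n_cases = n_cases,
                               missingness_rate = missingness, seed = seed)
  generate_cohort(cfg)
}

# compact phantom used where only structural invariants matter
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(64L, 64L, 32L), spacing = c(3, 3, 6), ...)
}

# exhaustive-threshold brute-force PR / ROC oracles (independent of the
# package implementation: direct confusion counting at every threshold)
brute_pr <- function(labels, probs) {
  thr <- sort(unique(probs), decreasing = TRUE)
  prec <- rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- probs >= thr[i]
    tp <- sum(pred & labels == 1)
    prec[i] <- tp / sum(pred)
    rec[i] <- tp / sum(labels == 1)
  }
  list(precision = prec, recall = rec,
       auprc = sum(diff(c(0, rec)) * prec))
}

brute_roc <- function(labels, probs) {
  # normalized Mann-Whitney U with ties counted half
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# permutation-average Shapley oracle: mean marginal contribution over all
# d! orderings, computed directly from the definition
perm_oracle <- function(model_fn, instance, background, d) {
  bg <- as.matrix(background)
  coalition_value <- function(active) {
    rows <- bg
    if (any(active))
      rows[, active] <- matrix(instance[active], nrow(bg), sum(active),
                               byrow = TRUE)
    mean(model_fn(rows))
  }
  perms <- gtools_permutations(d)
  phi <- numeric(d)
  for (r in seq_len(nrow(perms))) {
    active <- logical(d)
    prev <- coalition_value(active)
    for (j in perms[r, ]) {
      active[j] <- TRUE
      cur <- coalition_value(active)
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / nrow(perms)
}

# all permutations of 1..d (recursive, tiny d only)
gtools_permutations <- function(d) {
  if (d == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(d - 1)
  out <- NULL
  for (k in seq_len(d)) {
    rest <- setdiff(seq_len(d), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

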