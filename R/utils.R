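#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Derive a reproducible child seed from a master seed
#'
#' Stage seeds are derived deterministically from one master seed so that a
#' whole pipeline run is reproducible from a single integer, while stages
#' remain decoupled (changing one stage's draws does not perturb another's).
#'
#' @param master integer master seed.
#' @param label character label of the consuming stage.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  # small rolling hash of label, folded with the master seed; kept < 2^31
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147483629)
}

# Quantile of a normal truncated to [lo, hi]; u in (0,1).
qtrunc_norm <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary_mask <- function(m) all(m %in% c(0L, 1L, FALSE, TRUE))
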