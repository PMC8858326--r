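# Model fitting: penalised logistic, FCNN, two-timestep LSTM -------------

#' Model specification
#'
#' Hyperparameters for one classifier. `kind` selects L2-penalised logistic
#' regression (`"logistic"`), a two-hidden-layer feed-forward network
#' (`"fcnn"`), or the two-timestep recurrent memory network (`"lstm"`).
#' All fits weight the loss inversely to class prevalence; networks use
#' dropout, L2 weight decay, Adam and early stopping on a stratified
#' internal validation split.
#'
#' @param kind one of `"logistic"`, `"fcnn"`, `"lstm"`.
#' @param hidden hidden width (both layers for the FCNN; memory size for
#'   the LSTM).
#' @param dropout dropout rate in `[0, 1)`.
#' @param l2 L2 penalty strength.
#' @param lr Adam learning rate.
#' @param max_epochs,patience early-stopping controls.
#' @param seed integer seed (initialisation, dropout, validation split).
#' @param class_weight class-weighting scheme: `"inverse"` (inverse
#'   prevalence), `"sqrt"` (square root of inverse prevalence, tempered),
#'   or `"none"`.
#' @param restarts number of independent network restarts whose predicted
#'   probabilities are averaged (variance reduction; ignored for logistic).
#' @param val_frac fraction of the training rows held out (stratified) for
#'   early stopping; `0` disables early stopping and trains for
#'   `max_epochs` on all rows.
#' @param grid optional list of named lists overriding hyperparameters
#'   during inner-loop model selection in [nested_cv()].
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("logistic", "fcnn", "lstm"), hidden = 16L,
                       dropout = 0.2, l2 = 1e-3, lr = 1e-2,
                       max_epochs = 300L, patience = 20L, seed = 1L,
                       restarts = 1L, val_frac = 0.15,
                       class_weight = c("inverse", "sqrt", "none"),
                       grid = NULL) {
  class_weight <- match.arg(class_weight)
  kind <- match.arg(kind)
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  if (l2 < 0 || lr <= 0) stop_config("l2 must be >= 0 and lr > 0")
  if (val_frac < 0 || val_frac >= 0.5)
    stop_config("val_frac must be in [0, 0.5)")
  structure(list(kind = kind, hidden = as.integer(hidden), dropout = dropout,
                 l2 = l2, lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 restarts = as.integer(restarts), val_frac = val_frac,
                 class_weight = class_weight, grid = grid),
            class = "model_spec")
}

# default inner-selection grids, kept small enough for one CPU
default_grid <- function(kind) {
  if (kind == "logistic") {
    list(list(l2 = 1e-4), list(l2 = 1e-3), list(l2 = 1e-2), list(l2 = 1e-1))
  } else {
    list(list(hidden = 8L, l2 = 1e-4), list(hidden = 8L, l2 = 1e-2),
         list(hidden = 16L, l2 = 1e-4), list(hidden = 16L, l2 = 1e-2))
  }
}

#' Fit an L2-penalised logistic regression
#'
#' Ridge logistic regression (via glmnet) with class weights inverse to
#' prevalence; expects a standardized design matrix (see
#' [fit_preprocessor()]).
#'
#' @param x numeric matrix (n x d), already standardized.
#' @param y binary labels.
#' @param spec a [model_spec()] with `kind = "logistic"`.
#' @return A fitted model of class `edema_model`.
#' @export
fit_logistic <- function(x, y, spec = model_spec("logistic")) {
  check_labels(y)
  x <- as.matrix(x)
  padded <- FALSE
  if (ncol(x) < 2) { # glmnet needs >= 2 columns
    x <- cbind(x, .pad = 0)
    padded <- TRUE
  }
  w <- class_weights(y, spec$class_weight %||% "inverse")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = spec$l2, weights = w, standardize = FALSE)
  structure(list(kind = "logistic", fit = fit, spec = spec, padded = padded,
                 coef = stats::setNames(as.numeric(stats::coef(fit)),
                                        rownames(stats::coef(fit)))),
            class = "edema_model")
}

#' Fit the feed-forward network
#'
#' Two hidden relu layers of width `spec$hidden`, inverted dropout, L2
#' decay, Adam, early stopping on a stratified 15% validation split, class
#' weighting. Deterministic per `spec$seed`.
#'
#' @inheritParams fit_logistic
#' @return A fitted `edema_model`.
#' @export
fit_fcnn <- function(x, y, spec = model_spec("fcnn")) {
  check_labels(y, allow_single = TRUE)
  x <- as.matrix(x)
  members <- lapply(seq_len(spec$restarts), function(r) {
    withr::with_seed(derive_seed(spec$seed, paste0("fcnn", r)), {
      train_net_once(y, spec,
        init = function() fcnn_init(ncol(x), spec$hidden, spec$hidden),
        grad_fn = function(p, rows, w, dropmask) {
          fw <- fcnn_forward(p, x[rows, , drop = FALSE], dropmask[[1]],
                             dropmask[[2]])
          fcnn_backward(p, x[rows, , drop = FALSE], y[rows], w, fw,
                        spec$l2, dropmask[[1]], dropmask[[2]])
        },
        eval_fn = function(p, rows) fcnn_forward(p, x[rows, , drop = FALSE])$p,
        n_masks = 2L)
    })
  })
  structure(list(kind = "fcnn", members = members, spec = spec),
            class = "edema_model")
}

# shared restart body: stratified val split (or none), dropout masks, Adam
train_net_once <- function(y, spec, init, grad_fn, eval_fn, n_masks) {
  w_all <- class_weights(y, spec$class_weight %||% "inverse")
  use_val <- spec$val_frac > 0 && length(y) >= 10
  if (use_val) {
    sp <- val_split(y, spec$val_frac)
  } else {
    sp <- list(train = seq_along(y), val = seq_along(y))
  }
  keep <- 1 - spec$dropout
  nt <- length(sp$train)
  res <- train_network(
    init(),
    grad_train = function(p) {
      masks <- replicate(n_masks, {
        if (spec$dropout > 0)
          matrix(stats::rbinom(nt * spec$hidden, 1, keep) / keep, nt)
        else NULL
      }, simplify = FALSE)
      grad_fn(p, sp$train, w_all[sp$train], masks)
    },
    loss_val = function(p) wbce(eval_fn(p, sp$val), y[sp$val],
                                w_all[sp$val]),
    lr = spec$lr,
    max_epochs = spec$max_epochs,
    patience = if (use_val) spec$patience else spec$max_epochs
  )
  res$par
}

#' Fit the two-timestep recurrent memory network
#'
#' A standard gated memory-cell recurrence (sigmoid input/forget/output
#' gates, tanh candidate) unrolled over the two clinical timepoints; the
#' final hidden state feeds a sigmoid classification head with dropout.
#' Class-weighted loss, L2 decay, Adam, early stopping. Deterministic per
#' `spec$seed`.
#'
#' @param x_seq numeric array `n x 2 x d` (subjects x timesteps x slots),
#'   see [build_sequences()].
#' @inheritParams fit_logistic
#' @return A fitted `edema_model`.
#' @export
fit_lstm <- function(x_seq, y, spec = model_spec("lstm")) {
  check_labels(y, allow_single = TRUE)
  if (length(dim(x_seq)) != 3L || dim(x_seq)[2] != 2L)
    stop_config("x_seq must be an n x 2 x d array (two timesteps)")
  d <- dim(x_seq)[3]
  X1 <- matrix(x_seq[, 1, ], ncol = d)
  X2 <- matrix(x_seq[, 2, ], ncol = d)
  members <- lapply(seq_len(spec$restarts), function(r) {
    withr::with_seed(derive_seed(spec$seed, paste0("lstm", r)), {
      train_net_once(y, spec,
        init = function() lstm_init(d, spec$hidden),
        grad_fn = function(p, rows, w, dropmask) {
          fw <- lstm_forward(p, X1[rows, , drop = FALSE],
                             X2[rows, , drop = FALSE], dropmask[[1]])
          lstm_backward(p, X1[rows, , drop = FALSE],
                        X2[rows, , drop = FALSE], y[rows], w, fw,
                        spec$l2, dropmask[[1]])
        },
        eval_fn = function(p, rows) {
          lstm_forward(p, X1[rows, , drop = FALSE],
                       X2[rows, , drop = FALSE])$p
        },
        n_masks = 1L)
    })
  })
  structure(list(kind = "lstm", members = members, spec = spec),
            class = "edema_model")
}

check_labels <- function(y, allow_single = FALSE) {
  if (!all(y %in% c(0, 1))) stop_config("labels must be binary 0/1")
  if (!allow_single && length(unique(y)) < 2)
    stop_config("need both classes to fit this model")
}

#' Predicted probabilities from a fitted model
#'
#' @param model an `edema_model`.
#' @param x design matrix (logistic/fcnn) or `n x 2 x d` sequence array
#'   (lstm), preprocessed the same way as the training data.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "edema_model"))
  switch(model$kind,
    logistic = {
      x <- as.matrix(x)
      if (model$padded) x <- cbind(x, .pad = 0)
      as.numeric(stats::predict(model$fit, newx = x, type = "response"))
    },
    fcnn = {
      xm <- as.matrix(x)
      rowMeans(vapply(model$members,
                      function(par) fcnn_forward(par, xm)$p,
                      numeric(nrow(xm))))
    },
    lstm = {
      X1 <- matrix(x[, 1, ], ncol = dim(x)[3])
      X2 <- matrix(x[, 2, ], ncol = dim(x)[3])
      rowMeans(vapply(model$members,
                      function(par) lstm_forward(par, X1, X2)$p,
                      numeric(nrow(X1))))
    }
  )
}
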