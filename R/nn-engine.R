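# Small neural-network engine: feed-forward and two-timestep LSTM --------
#
# Full-batch training with Adam, inverted dropout, L2 weight decay, class
# weighting and early stopping on a stratified internal validation split.
# Gradients are hand-derived and checked against finite differences in the
# test suite. Everything is deterministic given the model seed.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) x * (x > 0)

# weighted binary cross-entropy; probs clipped away from {0,1}
wbce <- function(p, y, w) {
  p <- clamp(p, 1e-12, 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log1p(-p))) / sum(w)
}

class_weights <- function(y, scheme = c("inverse", "sqrt", "none")) {
  scheme <- match.arg(scheme)
  n <- length(y)
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == n || scheme == "none") return(rep(1, n))
  w <- ifelse(y == 1, n / (2 * n1), n / (2 * (n - n1)))
  if (scheme == "sqrt") w <- sqrt(w)
  w
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# stratified train/validation split indices (val gets >=1 of each class
# when possible)
val_split <- function(y, frac = 0.15) {
  idx1 <- sample(which(y == 1))
  idx0 <- sample(which(y == 0))
  n1 <- max(if (length(idx1) > 1) 1L else 0L, round(frac * length(idx1)))
  n0 <- max(1L, round(frac * length(idx0)))
  val <- c(idx1[seq_len(min(n1, length(idx1)))], idx0[seq_len(n0)])
  list(train = setdiff(seq_along(y), val), val = val)
}

# ---- feed-forward network ----------------------------------------------

fcnn_init <- function(d, h1, h2) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  list(W1 = he(d, h1), b1 = rep(0, h1),
       W2 = he(h1, h2), b2 = rep(0, h2),
       W3 = he(h2, 1), b3 = 0)
}

fcnn_forward <- function(par, X, drop1 = NULL, drop2 = NULL) {
  A1 <- relu(sweep(X %*% par$W1, 2, par$b1, "+"))
  if (!is.null(drop1)) A1 <- A1 * drop1
  A2 <- relu(sweep(A1 %*% par$W2, 2, par$b2, "+"))
  if (!is.null(drop2)) A2 <- A2 * drop2
  logit <- drop(A2 %*% par$W3) + par$b3
  list(A1 = A1, A2 = A2, logit = logit, p = sigmoid(logit))
}

fcnn_backward <- function(par, X, y, w, fw, l2, drop1, drop2) {
  n <- nrow(X)
  dlogit <- w * (fw$p - y) / sum(w)
  gW3 <- crossprod(fw$A2, dlogit) + 2 * l2 * par$W3
  gb3 <- sum(dlogit)
  dA2 <- outer(dlogit, drop(par$W3))
  if (!is.null(drop2)) dA2 <- dA2 * drop2
  dZ2 <- dA2 * (fw$A2 > 0)
  gW2 <- crossprod(fw$A1, dZ2) + 2 * l2 * par$W2
  gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(par$W2)
  if (!is.null(drop1)) dA1 <- dA1 * drop1
  dZ1 <- dA1 * (fw$A1 > 0)
  gW1 <- crossprod(X, dZ1) + 2 * l2 * par$W1
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

fcnn_loss <- function(par, X, y, w, l2) {
  fw <- fcnn_forward(par, X)
  wbce(fw$p, y, w) + l2 * (sum(par$W1^2) + sum(par$W2^2) + sum(par$W3^2))
}

# ---- two-timestep LSTM --------------------------------------------------
# Gate layout within the 4h columns: input, forget, candidate, output.

lstm_init <- function(d, h) {
  sc <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(1 / nin)), nin, nout)
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias init
  list(Wx = sc(d, 4 * h), Wh = sc(h, 4 * h), b = b,
       Wo = sc(h, 1), bo = 0)
}

lstm_gates <- function(z, h) {
  list(i = sigmoid(z[, 1:h, drop = FALSE]),
       f = sigmoid(z[, (h + 1):(2 * h), drop = FALSE]),
       g = tanh(z[, (2 * h + 1):(3 * h), drop = FALSE]),
       o = sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE]))
}

lstm_forward <- function(par, X1, X2, drop = NULL) {
  h <- nrow(par$Wh)
  z1 <- sweep(X1 %*% par$Wx, 2, par$b, "+")
  g1 <- lstm_gates(z1, h)
  c1 <- g1$i * g1$g
  u1 <- tanh(c1)
  h1 <- g1$o * u1
  z2 <- sweep(X2 %*% par$Wx + h1 %*% par$Wh, 2, par$b, "+")
  g2 <- lstm_gates(z2, h)
  c2 <- g2$f * c1 + g2$i * g2$g
  u2 <- tanh(c2)
  h2 <- g2$o * u2
  h2d <- if (is.null(drop)) h2 else h2 * drop
  logit <- drop(h2d %*% par$Wo) + par$bo
  list(g1 = g1, c1 = c1, u1 = u1, h1 = h1,
       g2 = g2, c2 = c2, u2 = u2, h2 = h2, h2d = h2d,
       logit = logit, p = sigmoid(logit))
}

lstm_backward <- function(par, X1, X2, y, w, fw, l2, drop = NULL) {
  h <- nrow(par$Wh)
  dlogit <- w * (fw$p - y) / sum(w)
  gWo <- crossprod(fw$h2d, dlogit) + 2 * l2 * par$Wo
  gbo <- sum(dlogit)
  dh2 <- outer(dlogit, drop(par$Wo))
  if (!is.null(drop)) dh2 <- dh2 * drop
  g2 <- fw$g2
  do2 <- dh2 * fw$u2
  dc2 <- dh2 * g2$o * (1 - fw$u2^2)
  di2 <- dc2 * g2$g
  df2 <- dc2 * fw$c1
  dg2 <- dc2 * g2$i
  dz2 <- cbind(di2 * g2$i * (1 - g2$i),
               df2 * g2$f * (1 - g2$f),
               dg2 * (1 - g2$g^2),
               do2 * g2$o * (1 - g2$o))
  dc1 <- dc2 * g2$f
  dh1 <- dz2 %*% t(par$Wh)
  g1 <- fw$g1
  do1 <- dh1 * fw$u1
  dc1 <- dc1 + dh1 * g1$o * (1 - fw$u1^2)
  di1 <- dc1 * g1$g
  dg1 <- dc1 * g1$i
  dz1 <- cbind(di1 * g1$i * (1 - g1$i),
               matrix(0, nrow(dz2), h),
               dg1 * (1 - g1$g^2),
               do1 * g1$o * (1 - g1$o))
  list(Wx = crossprod(X1, dz1) + crossprod(X2, dz2) + 2 * l2 * par$Wx,
       Wh = crossprod(fw$h1, dz2) + 2 * l2 * par$Wh,
       b = colSums(dz1) + colSums(dz2),
       Wo = gWo, bo = gbo)
}

lstm_loss <- function(par, X1, X2, y, w, l2) {
  fw <- lstm_forward(par, X1, X2)
  wbce(fw$p, y, w) +
    l2 * (sum(par$Wx^2) + sum(par$Wh^2) + sum(par$Wo^2))
}

# ---- shared training loop ----------------------------------------------

# Generic full-batch Adam loop: grad_train(par) returns gradients,
# loss_val(par) the monitored loss; the best-validation parameters win.
train_network <- function(par, grad_train, loss_val,
                          lr, max_epochs, patience) {
  state <- adam_state(par)
  best <- list(par = par, val = loss_val(par), epoch = 0L)
  waited <- 0L
  history <- numeric(0)
  for (t in seq_len(max_epochs)) {
    g <- grad_train(par)
    upd <- adam_update(par, g, state, lr, t)
    par <- upd$params
    state <- upd$state
    lv <- loss_val(par)
    if (!is.finite(lv)) stop_config("NaN/Inf loss at epoch %d; aborting", t)
    history[t] <- lv
    if (lv < best$val - 1e-7) {
      best <- list(par = par, val = lv, epoch = t)
      waited <- 0L
    } else {
      waited <- waited + 1L
      if (waited >= patience) break
    }
  }
  list(par = best$par, val = best$val, epochs = length(history),
       best_epoch = best$epoch, history = history)
}
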