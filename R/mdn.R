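# Conditional mixture-density network: a small fully-connected net mapping
# the three raster features to the parameters of a Gaussian mixture over
# (G_I, G_E).  Written in plain R (matrix algebra + hand-derived gradients,
# Adam optimizer); with ~150 training records and two hidden layers of 64
# units a full training takes a couple of seconds.

.mdn_init <- function(n_in, hidden, k, n_out, seed) {
  set.seed(seed)
  gl <- function(a, b) matrix(rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
  n_head <- k + 2 * k * n_out
  b3 <- numeric(n_head)
  b3[(k + 1):(k + k * n_out)] <- runif(k * n_out)       # spread means over [0,1]
  b3[(k + k * n_out + 1):n_head] <- log(0.25)           # moderate initial SDs
  list(W1 = gl(n_in, hidden), b1 = numeric(hidden),
       W2 = gl(hidden, hidden), b2 = numeric(hidden),
       W3 = gl(hidden, n_head) * 0.1, b3 = b3,
       k = k, n_in = n_in, n_out = n_out, hidden = hidden)
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# forward pass; returns activations and mixture parameters
.mdn_forward <- function(net, X) {
  H1 <- tanh(sweep(X %*% net$W1, 2, net$b1, `+`))
  H2 <- tanh(sweep(H1 %*% net$W2, 2, net$b2, `+`))
  O <- sweep(H2 %*% net$W3, 2, net$b3, `+`)
  k <- net$k; d <- net$n_out
  logits <- O[, 1:k, drop = FALSE]
  mu <- O[, (k + 1):(k + k * d), drop = FALSE]
  logsig <- pmin(pmax(O[, (k + k * d + 1):(k + 2 * k * d), drop = FALSE], -6), 2)
  logpi <- logits - .logsumexp_rows(logits)
  list(H1 = H1, H2 = H2, O = O, logits = logits, logpi = logpi,
       mu = mu, logsig = logsig)
}

# mean negative log-likelihood of Y (n x d, scaled) under the conditional
# mixture; optionally returns per-sample responsibilities for the backward
# pass
.mdn_nll <- function(net, fwd, Y, with_grad = FALSE) {
  k <- net$k; d <- net$n_out; n <- nrow(Y)
  ll_k <- fwd$logpi                                    # n x k, accumulate
  for (j in seq_len(d)) {
    mu_j <- fwd$mu[, ((j - 1) * k + 1):(j * k), drop = FALSE]
    ls_j <- fwd$logsig[, ((j - 1) * k + 1):(j * k), drop = FALSE]
    z <- (Y[, j] - mu_j) / exp(ls_j)
    ll_k <- ll_k - 0.5 * z^2 - ls_j - 0.5 * log(2 * pi)
  }
  lse <- .logsumexp_rows(ll_k)
  nll <- -mean(lse)
  if (!with_grad) return(nll)
  gamma <- exp(ll_k - lse)                             # responsibilities
  dO <- matrix(0, n, ncol(fwd$O))
  dO[, 1:k] <- (exp(fwd$logpi) - gamma) / n
  for (j in seq_len(d)) {
    mu_j <- fwd$mu[, ((j - 1) * k + 1):(j * k), drop = FALSE]
    ls_j <- fwd$logsig[, ((j - 1) * k + 1):(j * k), drop = FALSE]
    sig2 <- exp(2 * ls_j)
    dO[, k + (j - 1) * k + (1:k)] <- gamma * (mu_j - Y[, j]) / sig2 / n
    dO[, k + k * d + (j - 1) * k + (1:k)] <-
      gamma * (1 - (Y[, j] - mu_j)^2 / sig2) / n
  }
  list(nll = nll, dO = dO)
}

.mdn_backward <- function(net, fwd, X, dO) {
  dW3 <- t(fwd$H2) %*% dO
  db3 <- colSums(dO)
  dH2 <- dO %*% t(net$W3) * (1 - fwd$H2^2)
  dW2 <- t(fwd$H1) %*% dH2
  db2 <- colSums(dH2)
  dH1 <- dH2 %*% t(net$W2) * (1 - fwd$H1^2)
  dW1 <- t(X) %*% dH1
  db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

# full-batch Adam with a validation split and early stopping on the
# validation NLL; returns the best-validation weights
.mdn_train <- function(X, Y, k = 8, hidden = 64, epochs = 500, lr = 1e-2,
                       val_frac = 0.1, patience = 100, seed = 1) {
  n <- nrow(X)
  set.seed(derive_seed(seed, "mdn-split"))
  n_val <- max(1L, round(val_frac * n))
  vi <- sample.int(n, n_val)
  Xt <- X[-vi, , drop = FALSE]; Yt <- Y[-vi, , drop = FALSE]
  Xv <- X[vi, , drop = FALSE];  Yv <- Y[vi, , drop = FALSE]
  net <- .mdn_init(ncol(X), hidden, k, ncol(Y), derive_seed(seed, "mdn-init"))
  wn <- c("W1", "b1", "W2", "b2", "W3", "b3")
  m <- v <- lapply(net[wn], function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(nll = Inf, net = net); wait <- 0
  for (ep in seq_len(epochs)) {
    fwd <- .mdn_forward(net, Xt)
    g <- .mdn_nll(net, fwd, Yt, with_grad = TRUE)
    if (!is.finite(g$nll))
      stop("training failure: non-finite loss at epoch ", ep)
    grad <- .mdn_backward(net, fwd, Xt, g$dO)
    for (w in wn) {
      m[[w]] <- b1 * m[[w]] + (1 - b1) * grad[[w]]
      v[[w]] <- b2 * v[[w]] + (1 - b2) * grad[[w]]^2
      mh <- m[[w]] / (1 - b1^ep); vh <- v[[w]] / (1 - b2^ep)
      net[[w]] <- net[[w]] - lr * mh / (sqrt(vh) + eps)
    }
    nll_v <- .mdn_nll(net, .mdn_forward(net, Xv), Yv)
    if (nll_v < best$nll - 1e-6) {
      best <- list(nll = nll_v, net = net); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  best$net$val_nll <- best$nll
  best$net$epochs_run <- ep
  best$net
}

# mixture parameters at a single conditioning point x (length n_in)
.mdn_cond <- function(net, x) {
  fwd <- .mdn_forward(net, matrix(x, 1))
  k <- net$k; d <- net$n_out
  list(pi = exp(drop(fwd$logpi)),
       mu = matrix(drop(fwd$mu), k, d),
       sig = matrix(exp(drop(fwd$logsig)), k, d))
}
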