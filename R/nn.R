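# Minimal fully-connected network engine.
#
# Networks are lists of weight matrices W[[l]] (d_{l-1} x d_l) and bias
# vectors b[[l]]; hidden layers share one activation, the output layer is
# linear. Everything is vectorized over rows (observations). Gradients are
# exact analytic backprop; the WGAN-GP critic additionally needs the
# gradient, with respect to the weights, of the network's gradient with
# respect to one input coordinate ("double backprop") — implemented below
# for smooth activations and verified against finite differences in the
# test suite.

act_fun <- function(name) {
  switch(name,
    relu = list(
      f  = function(a) pmax(a, 0),
      d1 = function(a, h) (a > 0) * 1,
      d2 = function(a, h) a * 0),
    tanh = list(
      f  = function(a) tanh(a),
      d1 = function(a, h) 1 - h^2,
      d2 = function(a, h) -2 * h * (1 - h^2)),
    softplus = list(
      f  = function(a) log1p(exp(-abs(a))) + pmax(a, 0),
      d1 = function(a, h) 1 / (1 + exp(-a)),
      d2 = function(a, h) { s <- 1 / (1 + exp(-a)); s * (1 - s) }),
    stop("unknown activation: ", name, call. = FALSE))
}

nn_init <- function(in_dim, hidden_sizes, out_dim, activation = "relu") {
  sizes <- c(in_dim, hidden_sizes, out_dim)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sdw <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, sdw),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, activation = activation, sizes = sizes)
}

add_bias <- function(A, b) A + rep(b, each = nrow(A))

nn_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  act <- act_fun(net$activation)
  H <- vector("list", L)      # H[[l]] = activation output of layer l (l < L)
  A <- vector("list", L)      # pre-activations
  h <- X
  for (l in seq_len(L)) {
    a <- add_bias(h %*% net$W[[l]], net$b[[l]])
    A[[l]] <- a
    if (l < L) { h <- act$f(a); H[[l]] <- h } else h <- a
  }
  if (keep) list(out = h, A = A, H = H, X = X) else list(out = h)
}

nn_predict <- function(net, X) nn_forward(net, X)$out

# Backprop: d_out is the n x out_dim matrix dLoss/d(output).
# Returns weight/bias gradients and optionally the gradient wrt X.
nn_backward <- function(net, cache, d_out, want_dx = FALSE) {
  L <- length(net$W)
  act <- act_fun(net$activation)
  gW <- vector("list", L); gb <- vector("list", L)
  D <- d_out
  for (l in L:1) {
    h_prev <- if (l == 1L) cache$X else cache$H[[l - 1L]]
    gW[[l]] <- crossprod(h_prev, D)
    gb[[l]] <- colSums(D)
    if (l > 1L || want_dx) {
      Dh <- D %*% t(net$W[[l]])
      if (l > 1L)
        D <- Dh * act$d1(cache$A[[l - 1L]], cache$H[[l - 1L]])
    }
  }
  list(gW = gW, gb = gb, dX = if (want_dx) Dh else NULL)
}

# Per-row derivative of the (scalar) network output with respect to input
# coordinate k. Returns the derivative vector g plus the intermediate
# directional derivatives needed by nn_grad_penalty_backward().
nn_input_grad <- function(net, cache, k) {
  L <- length(net$W)
  act <- act_fun(net$activation)
  n <- nrow(cache$X)
  S <- vector("list", L - 1L)  # s_l = t_{l-1} %*% W_l
  Tl <- vector("list", L - 1L) # t_l = phi'(a_l) * s_l
  s <- matrix(net$W[[1L]][k, ], n, ncol(net$W[[1L]]), byrow = TRUE)
  for (l in seq_len(L - 1L)) {
    if (l > 1L) s <- Tl[[l - 1L]] %*% net$W[[l]]
    S[[l]] <- s
    Tl[[l]] <- act$d1(cache$A[[l]], cache$H[[l]]) * s
  }
  g <- as.numeric(Tl[[L - 1L]] %*% net$W[[L]])
  list(g = g, S = S, Tl = Tl)
}

# Gradient, wrt all weights, of P = sum_i w_i * g_i where g_i is the
# derivative of the scalar output for row i wrt input coordinate k.
nn_grad_penalty_backward <- function(net, cache, ig, k, w) {
  L <- length(net$W)
  act <- act_fun(net$activation)
  gW <- lapply(net$W, function(m) m * 0)
  gb <- lapply(net$b, function(v) v * 0)
  # top layer: g = t_{L-1} %*% W_L
  gW[[L]] <- crossprod(ig$Tl[[L - 1L]], matrix(w, ncol = 1))
  tbar <- w %o% net$W[[L]][, 1L]
  hbar <- NULL
  for (l in (L - 1L):1L) {
    a <- cache$A[[l]]; h <- cache$H[[l]]
    p1 <- act$d1(a, h); p2 <- act$d2(a, h)
    abar <- tbar * p2 * ig$S[[l]]
    if (!is.null(hbar)) abar <- abar + hbar * p1
    h_prev <- if (l == 1L) cache$X else cache$H[[l - 1L]]
    gW[[l]] <- gW[[l]] + crossprod(h_prev, abar)
    gb[[l]] <- gb[[l]] + colSums(abar)
    tp <- tbar * p1
    if (l > 1L) {
      gW[[l]] <- gW[[l]] + crossprod(ig$Tl[[l - 1L]], tp)
      tbar <- tp %*% t(net$W[[l]])
      hbar <- abar %*% t(net$W[[l]])
    } else {
      gW[[1L]][k, ] <- gW[[1L]][k, ] + colSums(tp)
    }
  }
  list(gW = gW, gb = gb)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(net) {
  list(mW = lapply(net$W, function(m) m * 0),
       vW = lapply(net$W, function(m) m * 0),
       mb = lapply(net$b, function(v) v * 0),
       vb = lapply(net$b, function(v) v * 0),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

grad_global_norm <- function(grads) {
  sq <- sum(vapply(grads$gW, function(m) sum(m^2), numeric(1))) +
        sum(vapply(grads$gb, function(v) sum(v^2), numeric(1)))
  sqrt(sq)
}

clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  nrm <- grad_global_norm(grads)
  if (nrm > max_norm) {
    s <- max_norm / nrm
    grads$gW <- lapply(grads$gW, function(m) m * s)
    grads$gb <- lapply(grads$gb, function(v) v * s)
  }
  grads
}

grads_add <- function(g1, g2) {
  list(gW = Map(`+`, g1$gW, g2$gW), gb = Map(`+`, g1$gb, g2$gb))
}

# ---- Generic minibatch training loop ---------------------------------------
#
# loss_fn(out, rows) must return list(value = mean loss over the batch,
# grad = d(mean loss)/d(out), same shape as out). Rows index the full
# training matrix so the closure can look up its targets. A 10% slice of the
# rows is held out for early stopping (patience epochs without improvement).
nn_train_loop <- function(net, X, loss_fn, config, val_metric_fn = NULL) {
  if (is.null(val_metric_fn))
    val_metric_fn <- function(out, rows) loss_fn(out, rows)$value
  n <- nrow(X)
  n_val <- max(1L, floor(0.1 * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  state <- adam_init(net)
  best <- list(net = net, val = Inf, epoch = 0L)
  bs <- min(config$batch_size, length(tr_idx))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  epochs_run <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    # step-decayed learning rate: coarse fit first, precision polishing later
    lr <- config$learning_rate *
      0.3^(findInterval(epoch / config$max_epochs,
                        c(1 / 3, 2 / 3, 0.85, 0.95), left.open = TRUE))
    ord <- sample(tr_idx)
    n_batch <- ceiling(length(ord) / bs)
    tr_loss <- 0
    for (bi in seq_len(n_batch)) {
      rows <- ord[((bi - 1L) * bs + 1L):min(bi * bs, length(ord))]
      cache <- nn_forward(net, X[rows, , drop = FALSE], keep = TRUE)
      lf <- loss_fn(cache$out, rows)
      if (!is.finite(lf$value))
        stop(errorCondition(
          sprintf("training diverged (non-finite loss) at epoch %d", epoch),
          class = c("losrange_training_divergence", "error", "condition")))
      grads <- nn_backward(net, cache, lf$grad)
      if (!is.null(config$weight_decay) && config$weight_decay > 0)
        grads$gW <- Map(function(g, w) g + config$weight_decay * w,
                        grads$gW, net$W)
      grads <- clip_grads(grads, config$grad_clip_norm)
      st <- adam_step(net, grads, state, lr)
      net <- st$net; state <- st$state
      tr_loss <- tr_loss + lf$value * length(rows)
    }
    tr_loss <- tr_loss / length(tr_idx)
    val_out <- nn_predict(net, X[val_idx, , drop = FALSE])
    val_loss <- val_metric_fn(val_out, val_idx)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         val_loss = val_loss))
    epochs_run <- epoch
    if (is.finite(val_loss) && val_loss < best$val - 1e-10) {
      best <- list(net = net, val = val_loss, epoch = epoch)
    } else if (epoch - best$epoch >= config$early_stop_patience) {
      break
    }
  }
  list(net = best$net, history = history, best_epoch = best$epoch,
       epochs_run = epochs_run,
       converged = epochs_run < config$max_epochs)
}
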