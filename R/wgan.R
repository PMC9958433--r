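#' WGAN-GP training configuration
#'
#' Hyperparameters for the conditional Wasserstein GAN with gradient penalty.
#' Defaults follow the standard WGAN-GP recipe — penalty weight 10, five
#' critic updates per generator update, Adam with betas (0, 0.9) — except the
#' learning rate, which defaults to 5e-4: the conventional 1e-4 assumes
#' training budgets of ~1e5 generator steps, while this package targets
#' cohort-scale runs of a few thousand steps. 500 samples are generated per
#' patient when summarizing.
#'
#' @param noise_dim dimension of the generator's noise input (default 16).
#' @param n_critic critic updates per generator update (default 5).
#' @param gp_weight gradient-penalty weight (default 10).
#' @param learning_rate Adam learning rate for both networks (default 5e-4).
#' @param adam_betas length-2 Adam momentum parameters (default `c(0, 0.9)`).
#' @param max_epochs passes over the training rows (default 150).
#' @param batch_size minibatch size (default 256).
#' @param n_samples_per_patient default draw count for summaries (500).
#' @param hidden_sizes hidden widths of both networks (default `c(64, 64)`).
#' @param seed integer seed.
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(noise_dim = 16, n_critic = 5, gp_weight = 10,
                       learning_rate = 5e-4, adam_betas = c(0, 0.9),
                       max_epochs = 150, batch_size = 256,
                       n_samples_per_patient = 500,
                       hidden_sizes = c(64, 64), seed = 1L) {
  stopifnot(noise_dim >= 1, n_critic >= 1, gp_weight >= 0,
            learning_rate > 0, length(adam_betas) == 2,
            max_epochs >= 1, batch_size >= 1, n_samples_per_patient >= 1)
  structure(list(noise_dim = as.integer(noise_dim),
                 n_critic = as.integer(n_critic), gp_weight = gp_weight,
                 learning_rate = learning_rate, adam_betas = adam_betas,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 n_samples_per_patient = as.integer(n_samples_per_patient),
                 hidden_sizes = as.integer(hidden_sizes),
                 seed = as.integer(seed)),
            class = "gan_config")
}

# Critic objective terms on one batch (standardized units). The critic scores
# (features, LOS) pairs; the gradient penalty acts along the LOS coordinate
# at points interpolated between real and fake LOS values at fixed features.
wgan_critic_terms <- function(critic, X, l_real, l_fake, u, gp_weight) {
  k <- ncol(X) + 1L
  d_fake <- nn_predict(critic, cbind(X, l_fake))
  d_real <- nn_predict(critic, cbind(X, l_real))
  l_int <- u * l_real + (1 - u) * l_fake
  cache_i <- nn_forward(critic, cbind(X, l_int), keep = TRUE)
  g <- nn_input_grad(critic, cache_i, k)$g
  wass <- mean(d_fake) - mean(d_real)
  penalty <- gp_weight * mean((abs(g) - 1)^2)
  list(wass = wass, penalty = penalty, total = wass + penalty, g = g)
}

#' Train a conditional WGAN-GP for LOS
#'
#' The generator maps (features, noise) to a LOS sample; the critic scores
#' (features, LOS) pairs. Training alternates `n_critic` critic updates —
#' objective \eqn{E[D(x, \hat\ell)] - E[D(x, \ell)] + w_{gp}(\|\nabla_\ell
#' D\| - 1)^2} with the gradient taken along the LOS coordinate at
#' interpolated points — with one generator update minimizing
#' \eqn{-E[D(x, \hat\ell)]}. Features and LOS are standardized internally;
#' generated samples are returned in hours. The critic uses softplus hidden
#' units (the penalty needs a smooth activation); the generator uses ReLU.
#'
#' @param train imputed training [cohort_table()].
#' @param config a [gan_config()].
#' @return An object of class `gan_fit` holding generator, critic and a
#'   per-step training history.
#' @export
train_wgan_gp <- function(train, config = gan_config()) {
  stopifnot(inherits(train, "cohort_table"), inherits(config, "gan_config"))
  if (length(train$los_hours) == 0) stop("empty training cohort", call. = FALSE)
  set.seed(config$seed + 3L)
  encoder <- make_encoder(train$features)
  X <- encode_features(encoder, train$features)
  y <- train$los_hours
  y_center <- mean(y); y_scale <- max(sd(y), 1) # floor of 1 h for degenerate labels
  ys <- (y - y_center) / y_scale
  n <- nrow(X); d <- ncol(X)
  bs <- min(config$batch_size, n)
  nz <- config$noise_dim
  gen <- nn_init(d + nz, config$hidden_sizes, 1L, "relu")
  # softplus: smooth (the gradient penalty differentiates the critic's input
  # gradient) but non-saturating, unlike tanh which starves the generator
  critic <- nn_init(d + 1L, config$hidden_sizes, 1L, "softplus")
  st_g <- adam_init(gen); st_c <- adam_init(critic)
  b1 <- config$adam_betas[1]; b2 <- config$adam_betas[2]
  k <- d + 1L
  steps_per_epoch <- max(1L, floor(n / bs))
  history <- vector("list", config$max_epochs * steps_per_epoch)
  step <- 0L
  # adversarial losses oscillate; keep the generator checkpoint whose
  # generated first two moments best match the real ones on a fixed slice
  mon_idx <- sample.int(n, min(512L, n))
  mon_m <- mean(y[mon_idx]); mon_s <- sd(y[mon_idx])
  mon_noise <- matrix(rnorm(length(mon_idx) * nz), length(mon_idx), nz)
  best <- list(gen = gen, score = Inf)

  gen_fake <- function(Xb) {
    noise <- matrix(rnorm(nrow(Xb) * nz), nrow(Xb), nz)
    list(noise = noise,
         cache = nn_forward(gen, cbind(Xb, noise), keep = TRUE))
  }

  for (epoch in seq_len(config$max_epochs)) {
    # annealed like the supervised loop: coarse distribution matching first,
    # then smaller polishing steps
    lr <- config$learning_rate *
      0.3^(findInterval(epoch / config$max_epochs, c(1 / 2, 5 / 6),
                        left.open = TRUE))
    for (s in seq_len(steps_per_epoch)) {
      c_loss <- NA_real_
      for (ci in seq_len(config$n_critic)) {
        rows <- sample.int(n, bs)
        Xb <- X[rows, , drop = FALSE]
        l_real <- ys[rows]
        l_fake <- as.numeric(gen_fake(Xb)$cache$out)
        # fake/real score terms
        cache_f <- nn_forward(critic, cbind(Xb, l_fake), keep = TRUE)
        cache_r <- nn_forward(critic, cbind(Xb, l_real), keep = TRUE)
        g_f <- nn_backward(critic, cache_f, matrix(1 / bs, bs, 1))
        g_r <- nn_backward(critic, cache_r, matrix(-1 / bs, bs, 1))
        grads <- grads_add(g_f, g_r)
        # gradient penalty at interpolated LOS values
        u <- runif(bs)
        l_int <- u * l_real + (1 - u) * l_fake
        cache_i <- nn_forward(critic, cbind(Xb, l_int), keep = TRUE)
        ig <- nn_input_grad(critic, cache_i, k)
        pen_w <- config$gp_weight * 2 * (abs(ig$g) - 1) * sign(ig$g) / bs
        if (config$gp_weight > 0) {
          g_p <- nn_grad_penalty_backward(critic, cache_i, ig, k, pen_w)
          grads <- grads_add(grads, g_p)
        }
        c_loss <- mean(cache_f$out) - mean(cache_r$out) +
          config$gp_weight * mean((abs(ig$g) - 1)^2)
        if (!is.finite(c_loss))
          stop(errorCondition(
            sprintf("critic loss non-finite at epoch %d", epoch),
            class = c("losrange_training_divergence", "error", "condition")))
        st <- adam_step(critic, grads, st_c, lr, b1, b2)
        critic <- st$net; st_c <- st$state
      }
      # generator update
      rows <- sample.int(n, bs)
      Xb <- X[rows, , drop = FALSE]
      gf <- gen_fake(Xb)
      l_fake <- as.numeric(gf$cache$out)
      cache_c <- nn_forward(critic, cbind(Xb, l_fake), keep = TRUE)
      dD_dl <- nn_input_grad(critic, cache_c, k)$g
      g_loss <- -mean(cache_c$out)
      d_out <- matrix(-dD_dl / bs, ncol = 1)
      g_g <- nn_backward(gen, gf$cache, d_out)
      st <- adam_step(gen, g_g, st_g, lr, b1, b2)
      gen <- st$net; st_g <- st$state
      step <- step + 1L
      history[[step]] <- c(epoch = epoch, step = step,
                           critic_loss = c_loss, gen_loss = g_loss)
    }
    mon_out <- as.numeric(nn_predict(gen, cbind(X[mon_idx, , drop = FALSE],
                                                mon_noise)))
    # score on the reporting scale (hours, clamped at zero)
    mon_h <- pmax(mon_out * y_scale + y_center, 0)
    score <- abs(mean(mon_h) - mon_m) + 0.5 * abs(sd(mon_h) - mon_s)
    if (is.finite(score) && score < best$score)
      best <- list(gen = gen, score = score)
  }
  gen <- best$gen
  history <- as.data.frame(do.call(rbind, history[seq_len(step)]))
  structure(list(generator = gen, critic = critic, encoder = encoder,
                 y_center = y_center, y_scale = y_scale,
                 config = config, history = history),
            class = "gan_fit")
}

#' Generate LOS samples for one patient
#'
#' Draws `n` LOS samples from the trained conditional generator given one
#' patient's features, using fresh noise. Samples are clamped at 0 hours.
#'
#' @param bundle a `gan_fit` from [train_wgan_gp()].
#' @param features a one-row feature data frame (or one-row [cohort_table()])
#'   matching the training schema.
#' @param n number of samples (default: the config's 500).
#' @param seed optional seed for reproducible draws.
#' @return Numeric vector of `n` LOS samples in hours.
#' @export
sample_los <- function(bundle, features, n = bundle$config$n_samples_per_patient,
                       seed = NULL) {
  stopifnot(inherits(bundle, "gan_fit"), n >= 1)
  X <- encode_features(bundle$encoder, tab_features(features))
  if (nrow(X) != 1L) stop("`features` must contain exactly one row", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  noise <- matrix(rnorm(n * bundle$config$noise_dim), n)
  Xn <- cbind(X[rep(1L, n), , drop = FALSE], noise)
  out <- as.numeric(nn_predict(bundle$generator, Xn))
  pmax(out * bundle$y_scale + bundle$y_center, 0)
}

#' Per-patient generated-sample summaries for a whole table
#'
#' Draws `n` LOS samples per patient from the trained generator and reduces
#' each to (`mean_pred`, `std_pred`). Equivalent to looping [sample_los()]
#' plus [summarize_samples()] over the rows, but vectorized in blocks.
#'
#' @param bundle a `gan_fit` from [train_wgan_gp()].
#' @param table a [cohort_table()] matching the training schema.
#' @param n samples per patient (default: the config's 500).
#' @param seed optional seed for reproducible draws.
#' @param block patients per generation block (memory knob).
#' @return A data frame with one row per patient: `mean_pred`, `std_pred`
#'   (hours; population SD).
#' @export
predict_gan_summary <- function(bundle, table,
                                n = bundle$config$n_samples_per_patient,
                                seed = NULL, block = 100L) {
  stopifnot(inherits(bundle, "gan_fit"))
  X <- encode_features(bundle$encoder, tab_features(table))
  if (!is.null(seed)) set.seed(seed)
  np <- nrow(X)
  mean_pred <- numeric(np); std_pred <- numeric(np)
  nz <- bundle$config$noise_dim
  for (start in seq(1L, np, by = block)) {
    idx <- start:min(start + block - 1L, np)
    Xb <- X[rep(idx, each = n), , drop = FALSE]
    noise <- matrix(rnorm(nrow(Xb) * nz), nrow(Xb), nz)
    out <- as.numeric(nn_predict(bundle$generator, cbind(Xb, noise)))
    out <- pmax(out * bundle$y_scale + bundle$y_center, 0)
    sm <- matrix(out, nrow = n)
    mean_pred[idx] <- colMeans(sm)
    std_pred[idx] <- sqrt(colMeans(sm^2) - colMeans(sm)^2)
  }
  data.frame(mean_pred = mean_pred, std_pred = pmax(std_pred, 0))
}

#' Summarize generated LOS samples
#'
#' Reduces a vector of generated samples to the pair used for interval
#' construction: the arithmetic mean (`mean_pred`) and the standard deviation
#' (`std_pred`). The population SD (divisor n) is the default; at 500 samples
#' it differs from the sample SD by under 0.1%.
#'
#' @param samples numeric vector, length at least 2.
#' @param population use divisor n (default `TRUE`); `FALSE` for divisor n-1.
#' @return Named numeric vector `c(mean_pred =, std_pred =)`.
#' @export
summarize_samples <- function(samples, population = TRUE) {
  if (length(samples) < 2L)
    stop(errorCondition(
      "at least 2 samples are required to summarize a distribution",
      class = c("losrange_insufficient_samples", "error", "condition")))
  m <- mean(samples)
  v <- mean((samples - m)^2)
  if (!population) v <- v * length(samples) / (length(samples) - 1)
  c(mean_pred = m, std_pred = sqrt(v))
}
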