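#' Network training configuration
#'
#' @param hidden_sizes integer vector of hidden-layer widths (default
#'   `c(64, 64, 64)`).
#' @param activation hidden activation, `"relu"` (default), `"tanh"` or
#'   `"softplus"`.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 256).
#' @param max_epochs maximum training epochs (default 200).
#' @param early_stop_patience epochs without improvement on a 10% validation
#'   slice of the training set before stopping (default 10).
#' @param grad_clip_norm global gradient-norm clip; `NULL` selects the
#'   per-loss default (1.0 for the loss1/loss2 distributional objectives,
#'   whose flat regions destabilize training; off otherwise).
#' @param weight_decay L2 penalty on the weights (default 1e-3); curbs the
#'   memorization of pure-noise feature directions that otherwise deflates
#'   the training RMSE below the irreducible noise floor.
#' @param seed integer seed; fits are deterministic given config + data.
#' @param target_standardize standardize the training target to zero mean and
#'   unit SD during optimization and invert before reporting (default `TRUE`).
#' @return A list of class `net_config`.
#' @export
net_config <- function(hidden_sizes = c(64, 64, 64),
                       activation = c("relu", "tanh", "softplus"),
                       learning_rate = 1e-3,
                       batch_size = 256,
                       max_epochs = 200,
                       early_stop_patience = 10,
                       grad_clip_norm = NULL,
                       weight_decay = 1e-3,
                       seed = 1L,
                       target_standardize = TRUE) {
  activation <- match.arg(activation)
  stopifnot(all(hidden_sizes >= 1), learning_rate > 0, batch_size >= 1,
            max_epochs >= 1, early_stop_patience >= 1, weight_decay >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = activation,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 grad_clip_norm = grad_clip_norm,
                 weight_decay = weight_decay,
                 seed = as.integer(seed),
                 target_standardize = isTRUE(target_standardize)),
            class = "net_config")
}

# ---- feature encoding -------------------------------------------------------

make_encoder <- function(features) {
  if (anyNA(features))
    stop("features contain missing values; run impute_missing() first",
         call. = FALSE)
  xlev <- lapply(features, function(col) if (is.factor(col)) levels(col))
  xlev <- xlev[!vapply(xlev, is.null, logical(1))]
  X <- stats::model.matrix(~ . - 1, data = features)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(col_names = names(features), xlev = xlev,
       design_cols = colnames(X), center = center, scale = scale)
}

encode_features <- function(encoder, features) {
  missing_cols <- setdiff(encoder$col_names, names(features))
  extra_cols <- setdiff(names(features), encoder$col_names)
  if (length(missing_cols) || length(extra_cols))
    stop(errorCondition(
      sprintf("feature schema mismatch; missing: [%s], unexpected: [%s]",
              paste(missing_cols, collapse = ", "),
              paste(extra_cols, collapse = ", ")),
      class = c("losrange_feature_mismatch", "error", "condition")))
  features <- features[encoder$col_names]
  if (anyNA(features))
    stop("features contain missing values; run impute_missing() first",
         call. = FALSE)
  for (nm in names(encoder$xlev))
    features[[nm]] <- factor(features[[nm]], levels = encoder$xlev[[nm]])
  X <- stats::model.matrix(~ . - 1, data = features)
  X <- X[, encoder$design_cols, drop = FALSE]
  X <- sweep(X, 2, encoder$center)
  sweep(X, 2, encoder$scale, "/")
}

tab_features <- function(table) {
  if (inherits(table, "cohort_table")) table$features else as.data.frame(table)
}

# ---- point regressor --------------------------------------------------------

#' Train the point-prediction network
#'
#' A feed-forward regressor minimizing mean squared error on the LOS label.
#' The training-set RMSE is the global error scale of the `rmse` interval
#' method (the same width for every patient); a held-out RMSE is reported
#' separately when `test` is supplied.
#'
#' @param train a [cohort_table()], imputed (no missing entries).
#' @param config a [net_config()].
#' @param test optional held-out [cohort_table()] for `rmse_test`.
#' @return An object of class `regressor_fit` with elements `rmse_train`,
#'   `rmse_test` (or `NA`), `history` and `converged`.
#' @export
train_regressor <- function(train, config = net_config(), test = NULL) {
  stopifnot(inherits(train, "cohort_table"), inherits(config, "net_config"))
  if (length(train$los_hours) == 0) stop("empty training cohort", call. = FALSE)
  set.seed(config$seed)
  encoder <- make_encoder(train$features)
  X <- encode_features(encoder, train$features)
  y <- train$los_hours
  y_center <- if (config$target_standardize) mean(y) else 0
  y_scale <- if (config$target_standardize) max(sd(y), 1e-12) else 1
  ys <- (y - y_center) / y_scale
  net <- nn_init(ncol(X), config$hidden_sizes, 1L, config$activation)
  loss_fn <- function(out, rows) {
    r <- out[, 1] - ys[rows]
    list(value = mean(r^2), grad = matrix(2 * r / length(r), ncol = 1))
  }
  cfg <- config
  if (is.null(cfg$grad_clip_norm)) cfg$grad_clip_norm <- Inf
  res <- nn_train_loop(net, X, loss_fn, cfg)
  fit <- structure(list(net = res$net, encoder = encoder,
                        y_center = y_center, y_scale = y_scale,
                        config = config, history = res$history,
                        converged = res$converged),
                   class = "regressor_fit")
  fit$rmse_train <- sqrt(mean((predict_los(fit, train) - train$los_hours)^2))
  fit$rmse_test <- if (!is.null(test))
    sqrt(mean((predict_los(fit, test) - test$los_hours)^2)) else NA_real_
  fit
}

#' Predict LOS point values
#'
#' @param fit a `regressor_fit` from [train_regressor()].
#' @param table a [cohort_table()] (or bare feature data frame) matching the
#'   training schema.
#' @return Numeric vector of predicted LOS in hours, one per row.
#' @export
predict_los <- function(fit, table) {
  stopifnot(inherits(fit, "regressor_fit"))
  X <- encode_features(fit$encoder, tab_features(table))
  if (nrow(X) == 0) return(numeric(0))
  as.numeric(nn_predict(fit$net, X)) * fit$y_scale + fit$y_center
}

#' @export
print.regressor_fit <- function(x, ...) {
  cat(sprintf("<regressor_fit> rmse_train = %.2f h, rmse_test = %.2f h (%s)\n",
              x$rmse_train, x$rmse_test,
              if (x$converged) "early-stopped" else "max epochs reached"))
  invisible(x)
}

# ---- per-sample error network -----------------------------------------------

#' Train the per-sample error network
#'
#' A second network fit on the same features whose target is the base
#' regressor's per-row error. By default the target is the absolute error
#' `|LOS - LOS_pred|` and the output passes through a softplus transform, so
#' the predicted error — used as an interval half-width — is strictly
#' positive. With `signed = TRUE` the raw signed error is the target and the
#' prediction is used via its absolute value downstream.
#'
#' @param train imputed training [cohort_table()].
#' @param base a `regressor_fit` trained on the same schema.
#' @param config a [net_config()].
#' @param signed fit the signed error instead of its magnitude.
#' @return An object of class `error_net_fit`.
#' @export
train_error_net <- function(train, base, config = net_config(),
                            signed = FALSE) {
  stopifnot(inherits(train, "cohort_table"), inherits(base, "regressor_fit"))
  set.seed(config$seed + 1L)
  err <- train$los_hours - predict_los(base, train)
  target <- if (signed) err else abs(err)
  encoder <- make_encoder(train$features)
  X <- encode_features(encoder, train$features)
  e_scale <- if (config$target_standardize) max(sd(target), 1e-12) else 1
  e_center <- if (signed && config$target_standardize) mean(target) else 0
  ts <- (target - e_center) / e_scale
  net <- nn_init(ncol(X), config$hidden_sizes, 1L, config$activation)
  softplus <- function(o) log1p(exp(-abs(o))) + pmax(o, 0)
  loss_fn <- if (signed) {
    function(out, rows) {
      r <- out[, 1] - ts[rows]
      list(value = mean(r^2), grad = matrix(2 * r / length(r), ncol = 1))
    }
  } else {
    function(out, rows) {
      p <- softplus(out[, 1])
      r <- p - ts[rows]
      sg <- 1 / (1 + exp(-out[, 1]))
      list(value = mean(r^2), grad = matrix(2 * r * sg / length(r), ncol = 1))
    }
  }
  cfg <- config
  if (is.null(cfg$grad_clip_norm)) cfg$grad_clip_norm <- Inf
  res <- nn_train_loop(net, X, loss_fn, cfg)
  structure(list(net = res$net, encoder = encoder, base = base,
                 signed = signed, e_center = e_center, e_scale = e_scale,
                 config = config, history = res$history,
                 converged = res$converged),
            class = "error_net_fit")
}

#' Predict per-sample error magnitudes
#'
#' @param fit an `error_net_fit` from [train_error_net()].
#' @param table a [cohort_table()] matching the training schema.
#' @return Non-negative numeric vector (hours): the predicted error used as
#'   an interval half-width scale.
#' @export
predict_error <- function(fit, table) {
  stopifnot(inherits(fit, "error_net_fit"))
  X <- encode_features(fit$encoder, tab_features(table))
  if (nrow(X) == 0) return(numeric(0))
  o <- as.numeric(nn_predict(fit$net, X))
  if (fit$signed) abs(o * fit$e_scale + fit$e_center)
  else (log1p(exp(-abs(o))) + pmax(o, 0)) * fit$e_scale
}

# ---- distributional network -------------------------------------------------

#' Train the two-output distributional network
#'
#' A network with two output heads, \eqn{\mu_{pred}} and \eqn{z} with
#' \eqn{\sigma_{pred} = e^z > 0}, trained with one of the losses selected by
#' a [loss_config()] ([loss1()], [loss2()] or [loss3()]). When the target is
#' standardized (the default) the loss operates on the standardized scale:
#' loss1's \eqn{\pm 1} mass window and loss3's `lambda_penalty` are then in
#' standardized units, and `sigma0` (given in hours) is divided by the
#' target SD.
#'
#' Gradient clipping defaults on (global norm 1) for the loss1 and loss2
#' objectives, whose flat regions otherwise destabilize optimization. If
#' the fit hits `max_epochs` without the validation loss stalling, the
#' returned `status` records `"max_epochs_reached"` — expected behaviour for
#' loss1, which converges slowly.
#'
#' @param train imputed training [cohort_table()].
#' @param loss_cfg a [loss_config()].
#' @param config a [net_config()].
#' @return An object of class `dist_net_fit` with `status` and `history`.
#' @export
train_dist_net <- function(train, loss_cfg = loss_config("loss3"),
                           config = net_config()) {
  stopifnot(inherits(train, "cohort_table"), inherits(loss_cfg, "loss_config"))
  set.seed(config$seed + 2L)
  encoder <- make_encoder(train$features)
  X <- encode_features(encoder, train$features)
  y <- train$los_hours
  y_center <- if (config$target_standardize) mean(y) else 0
  y_scale <- if (config$target_standardize) max(sd(y), 1e-12) else 1
  ys <- (y - y_center) / y_scale
  sigma0s <- loss_cfg$sigma0 / y_scale
  net <- nn_init(ncol(X), config$hidden_sizes, 2L, config$activation)
  loss_fn <- function(out, rows) {
    lf <- dist_loss_impl(loss_cfg, out[, 1], out[, 2], ys[rows], sigma0s)
    n <- length(rows)
    list(value = mean(lf$value),
         grad = cbind(lf$d_mu / n, lf$d_z / n))
  }
  cfg <- config
  if (is.null(cfg$grad_clip_norm))
    cfg$grad_clip_norm <- if (loss_cfg$loss_id == "loss3") Inf else 1.0
  # loss1's value keeps shrinking as z collapses even when mu drifts, so its
  # raw value cannot select good weights; snapshot by validation mu error
  val_metric <- if (loss_cfg$loss_id == "loss1")
    function(out, rows) mean((out[, 1] - ys[rows])^2)
  res <- nn_train_loop(net, X, loss_fn, cfg, val_metric)
  structure(list(net = res$net, encoder = encoder,
                 y_center = y_center, y_scale = y_scale,
                 loss_cfg = loss_cfg, config = config,
                 history = res$history, converged = res$converged,
                 status = if (res$converged) "converged" else "max_epochs_reached"),
            class = "dist_net_fit")
}

#' Predict per-patient distribution parameters
#'
#' @param fit a `dist_net_fit` from [train_dist_net()].
#' @param table a [cohort_table()] matching the training schema.
#' @return A data frame with columns `mu_pred` and `sigma_pred` (hours);
#'   `sigma_pred` is strictly positive by the exponential parameterization.
#' @export
predict_dist <- function(fit, table) {
  stopifnot(inherits(fit, "dist_net_fit"))
  X <- encode_features(fit$encoder, tab_features(table))
  if (nrow(X) == 0)
    return(data.frame(mu_pred = numeric(0), sigma_pred = numeric(0)))
  out <- nn_predict(fit$net, X)
  data.frame(mu_pred = out[, 1] * fit$y_scale + fit$y_center,
             sigma_pred = exp(out[, 2]) * fit$y_scale)
}

#' @export
print.dist_net_fit <- function(x, ...) {
  cat(sprintf("<dist_net_fit> loss = %s, status = %s\n",
              x$loss_cfg$loss_id, x$status))
  invisible(x)
}
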