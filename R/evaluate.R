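#' Build per-patient LOS intervals
#'
#' Every method reduces to the same construction: interval
#' `center +/- alpha * scale`, where the scale is the method's per-patient
#' error quantity — the constant training RMSE (`rmse`), the predicted error
#' magnitude (`err_pred`), the predicted SD (`dis_loss1`–`dis_loss3`), or the
#' generated-sample SD (`wgan_gp`). Lower limits are clamped at 0 hours; the
#' clamp never changes coverage because true LOS is non-negative.
#'
#' @param method one of `"rmse"`, `"err_pred"`, `"dis_loss1"`, `"dis_loss2"`,
#'   `"dis_loss3"`, `"wgan_gp"`.
#' @param centers predicted LOS centers (hours).
#' @param scales non-negative per-patient error scales (hours); a length-1
#'   scale (e.g. a global RMSE) is recycled.
#' @param alpha non-negative width multiplier.
#' @return An object of class `interval_set` with `lower`, `upper`,
#'   `half_width`, `center`, `alpha` and `method`.
#' @export
build_intervals <- function(method = c("rmse", "err_pred", "dis_loss1",
                                       "dis_loss2", "dis_loss3", "wgan_gp"),
                            centers, scales, alpha) {
  method <- match.arg(method)
  if (length(scales) == 1L) scales <- rep(scales, length(centers))
  if (length(scales) != length(centers))
    stop("`centers` and `scales` must have equal length", call. = FALSE)
  if (any(scales < 0)) stop("`scales` must be non-negative", call. = FALSE)
  if (length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  hw <- alpha * scales
  structure(list(method = method, alpha = alpha, center = centers,
                 half_width = hw,
                 lower = pmax(centers - hw, 0), upper = centers + hw),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> method = %s, alpha = %.2f, n = %d, OPE = %.1f h\n",
              x$method, x$alpha, length(x$center),
              overall_prediction_error(x)))
  invisible(x)
}

#' Coverage accuracy of an interval set
#'
#' The fraction of patients whose true LOS falls inside their predicted
#' interval (closed on both ends).
#'
#' @param intervals an [build_intervals()] result.
#' @param los_true true LOS values (hours), same length.
#' @return A number in \[0, 1\].
#' @export
coverage_accuracy <- function(intervals, los_true) {
  stopifnot(inherits(intervals, "interval_set"))
  if (length(los_true) != length(intervals$center))
    stop("`los_true` length must match the interval set", call. = FALSE)
  mean(los_true >= intervals$lower & los_true <= intervals$upper)
}

#' Overall prediction error of an interval set
#'
#' The mean unclamped interval half-width, `alpha * mean(scale)` — the
#' width budget a method spends to reach its coverage. Exactly linear in
#' `alpha`.
#'
#' @param intervals an [build_intervals()] result.
#' @return Mean half-width in hours.
#' @export
overall_prediction_error <- function(intervals) {
  stopifnot(inherits(intervals, "interval_set"))
  mean(intervals$half_width)
}

# Smallest per-row alpha that covers the label. The 0-clamp on lower limits
# never binds for non-negative labels, so coverage(alpha) = P(|y - c| <= a*s).
alpha_required <- function(centers, scales, los_true) {
  a <- abs(los_true - centers) / scales
  a[abs(los_true - centers) == 0] <- 0 # covers scales == 0 at exact hit
  a
}

#' Calibrate the interval width multiplier
#'
#' Finds the smallest alpha on a grid of step `grid_step` whose coverage on
#' the given data reaches `target_accuracy`. Coverage is non-decreasing in
#' alpha, so the order statistics of the per-row required alphas give the
#' answer exactly; no search is needed.
#'
#' @param centers,scales per-patient interval centers and error scales (hours).
#' @param los_true true LOS values (hours).
#' @param target_accuracy required coverage, in (0, 1\].
#' @param grid_step alpha grid resolution (default 0.01).
#' @param alpha_max largest alpha considered before declaring the target
#'   unreachable (default 50).
#' @return An object of class `calibration_result`: `alpha_star`,
#'   `achieved_accuracy`, and `ope_at_alpha_star` (hours).
#' @export
calibrate_alpha <- function(centers, scales, los_true, target_accuracy = 0.95,
                            grid_step = 0.01, alpha_max = 50) {
  if (target_accuracy <= 0 || target_accuracy > 1)
    stop("`target_accuracy` must be in (0, 1]", call. = FALSE)
  if (grid_step <= 0) stop("`grid_step` must be positive", call. = FALSE)
  a_req <- alpha_required(centers, scales, los_true)
  n <- length(a_req)
  kth <- sort(a_req, partial = ceiling(target_accuracy * n))[ceiling(target_accuracy * n)]
  if (!is.finite(kth) || kth > alpha_max) {
    max_acc <- mean(a_req <= alpha_max)
    stop(errorCondition(
      sprintf("target accuracy %.3f unreachable for alpha <= %g (max achievable: %.3f)",
              target_accuracy, alpha_max, max_acc),
      class = c("losrange_calibration_error", "error", "condition")))
  }
  alpha_star <- ceiling(kth / grid_step - 1e-9) * grid_step
  structure(list(alpha_star = alpha_star,
                 achieved_accuracy = mean(a_req <= alpha_star),
                 ope_at_alpha_star = alpha_star * mean(scales),
                 target_accuracy = target_accuracy),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration> alpha* = %.2f, accuracy = %.3f (target %.2f), OPE = %.1f h\n",
              x$alpha_star, x$achieved_accuracy, x$target_accuracy,
              x$ope_at_alpha_star))
  invisible(x)
}

#' Coverage accuracy and width across an alpha grid
#'
#' @param centers,scales,los_true as in [calibrate_alpha()].
#' @param alpha_grid increasing vector of alpha values.
#' @return A data frame of class `eval_curve` with columns `alpha`,
#'   `accuracy` (non-decreasing) and `ope` (exactly linear in alpha).
#' @export
accuracy_curve <- function(centers, scales, los_true,
                           alpha_grid = seq(0, 4, by = 0.01)) {
  if (is.unsorted(alpha_grid, strictly = TRUE))
    stop("`alpha_grid` must be strictly increasing", call. = FALSE)
  a_req <- alpha_required(centers, scales, los_true)
  mean_scale <- mean(scales)
  out <- data.frame(alpha = alpha_grid,
                    accuracy = vapply(alpha_grid,
                                      function(a) mean(a_req <= a), numeric(1)),
                    ope = alpha_grid * mean_scale)
  class(out) <- c("eval_curve", "data.frame")
  out
}

#' Compare interval methods on a common test set
#'
#' For each supplied method, reports (a) the alpha and overall prediction
#' error at which the method reaches `target_accuracy`, and (b) the accuracy
#' the method achieves when every method is granted the same width budget
#' (the alpha is back-solved as `budget / mean(scale)`). Methods supplied as
#' `NULL` are reported as absent rather than failing.
#'
#' @param methods named list; each element is `list(centers =, scales =)` for
#'   one method (names should match the method enum of [build_intervals()]).
#' @param los_true true LOS values (hours) of the common test rows.
#' @param error_budgets width budgets in hours (default `c(48, 96)`).
#' @param target_accuracy coverage target (default 0.95).
#' @param grid_step alpha grid resolution (default 0.01).
#' @return A data frame with one row per method: `alpha_star`,
#'   `achieved_accuracy`, `ope_at_target`, and one `acc_at_<budget>` column
#'   per budget.
#' @export
compare_methods <- function(methods, los_true, error_budgets = c(48, 96),
                            target_accuracy = 0.95, grid_step = 0.01) {
  stopifnot(is.list(methods), length(names(methods)) == length(methods))
  rows <- lapply(names(methods), function(nm) {
    m <- methods[[nm]]
    base <- data.frame(method = nm, alpha_star = NA_real_,
                       achieved_accuracy = NA_real_, ope_at_target = NA_real_)
    for (b in error_budgets) base[[sprintf("acc_at_%g", b)]] <- NA_real_
    if (is.null(m)) return(base)
    cal <- tryCatch(
      calibrate_alpha(m$centers, m$scales, los_true, target_accuracy,
                      grid_step),
      losrange_calibration_error = function(e) NULL)
    if (!is.null(cal)) {
      base$alpha_star <- cal$alpha_star
      base$achieved_accuracy <- cal$achieved_accuracy
      base$ope_at_target <- cal$ope_at_alpha_star
    }
    a_req <- alpha_required(m$centers, m$scales, los_true)
    for (b in error_budgets) {
      alpha_b <- b / mean(m$scales)
      base[[sprintf("acc_at_%g", b)]] <- mean(a_req <= alpha_b)
    }
    base
  })
  do.call(rbind, rows)
}
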