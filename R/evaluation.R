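#' Relative root-mean-square error, in percent
#'
#' `sqrt(mean(((pred - real) / real)^2)) * 100`: the RMS of per-point
#' relative errors. Staircase targets are strictly positive by construction;
#' a near-zero true value is rejected loudly rather than silently producing
#' a huge ratio.
#'
#' @param y_pred,y_real equal-length numeric series.
#' @param epsilon guard on `|y_real|`.
#' @return relative RMSE in percent (scale-invariant, not shift-invariant).
#' @export
rmse_relative <- function(y_pred, y_real, epsilon = 1e-9) {
  stopifnot(length(y_pred) == length(y_real))
  if (any(abs(y_real) <= epsilon))
    stop("y_real contains values with |y| <= ", epsilon,
         "; relative error is degenerate", call. = FALSE)
  sqrt(mean(((y_pred - y_real) / y_real)^2)) * 100
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with SS_tot taken about the mean of the true
#' series. Equals 1 for a perfect fit and 0 for the constant-mean predictor;
#' can be negative for predictors worse than the mean.
#'
#' @param y_pred,y_real equal-length numeric series; `y_real` must not be
#'   constant.
#' @return R-squared (dimensionless, <= 1).
#' @export
r_squared <- function(y_pred, y_real) {
  stopifnot(length(y_pred) == length(y_real))
  ss_tot <- sum((y_real - mean(y_real))^2)
  if (ss_tot <= 0) stop("y_real is constant; R-squared undefined", call. = FALSE)
  1 - sum((y_pred - y_real)^2) / ss_tot
}

#' Evaluate a predicted staircase against the truth
#'
#' @param y_pred,y_real aligned series (one value per feature window).
#' @return an `evaluation_result`: both series, m, the true-series mean,
#'   relative RMSE (percent) and R-squared.
#' @export
evaluate_predictions <- function(y_pred, y_real) {
  stopifnot(length(y_pred) == length(y_real), length(y_real) >= 2)
  structure(list(y_pred = y_pred, y_real = y_real, m = length(y_real),
                 y_mean_real = mean(y_real),
                 rmse_relative = rmse_relative(y_pred, y_real),
                 r_squared = r_squared(y_pred, y_real)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation over %d points: relative RMSE %.3f%%, R2 %.4f\n",
              x$m, x$rmse_relative, x$r_squared))
  invisible(x)
}

#' Before/after adaptation deltas
#'
#' Per subject: delta RMSE = before - after (positive = improvement) and
#' delta R2 = after - before. The cohort report averages deltas over
#' subjects.
#'
#' @param before,after lists of `evaluation_result` (or of adaptation
#'   records with `rmse_before`/`rmse_after`/`r2_before`/`r2_after`), one
#'   per subject, in matching order.
#' @return list with `per_subject` data.frame and cohort means
#'   `mean_delta_rmse`, `mean_delta_r2`.
#' @export
adaptation_report <- function(before, after) {
  if (length(before) != length(after))
    stop("before/after subject lists differ in length", call. = FALSE)
  rows <- lapply(seq_along(before), function(i) {
    b <- before[[i]]; a <- after[[i]]
    if (!is.null(b[["m"]]) && !is.null(a[["m"]]) && b[["m"]] != a[["m"]])
      stop("subject ", i, ": before/after evaluated on different rows", call. = FALSE)
    data.frame(subject = i,
               rmse_before = b[["rmse_relative"]] %||% b[["rmse_before"]],
               rmse_after = a[["rmse_relative"]] %||% a[["rmse_after"]],
               r2_before = b[["r_squared"]] %||% b[["r2_before"]],
               r2_after = a[["r_squared"]] %||% a[["r2_after"]])
  })
  per <- do.call(rbind, rows)
  per$delta_rmse <- per$rmse_before - per$rmse_after
  per$delta_r2 <- per$r2_after - per$r2_before
  list(per_subject = per,
       mean_delta_rmse = mean(per$delta_rmse),
       mean_delta_r2 = mean(per$delta_r2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlay plot of true and predicted staircases
#'
#' Reproduces the usual before/after-adaptation overlay: the true staircase
#' with the pre- and (optionally) post-adaptation predictions against window
#' time.
#'
#' @param times window times (s).
#' @param y_real true staircase.
#' @param y_pred predicted staircase (pre-adaptation).
#' @param y_pred_adapted optional post-adaptation prediction.
#' @param ylab y-axis label (units of the gait parameter).
#' @return invisibly, NULL; draws on the current device.
#' @export
plot_staircase_fit <- function(times, y_real, y_pred, y_pred_adapted = NULL,
                               ylab = "gait parameter") {
  rng <- range(y_real, y_pred, y_pred_adapted)
  graphics::plot(times, y_real, type = "s", lwd = 2, ylim = rng,
                 xlab = "time (s)", ylab = ylab)
  graphics::lines(times, y_pred, type = "s", col = "#d95f02")
  legend_items <- c("true", "predicted")
  cols <- c("black", "#d95f02")
  if (!is.null(y_pred_adapted)) {
    graphics::lines(times, y_pred_adapted, type = "s", col = "#1b9e77")
    legend_items <- c(legend_items, "adapted")
    cols <- c(cols, "#1b9e77")
  }
  graphics::legend("topleft", legend = legend_items, col = cols, lwd = c(2, 1, 1),
                   bty = "n")
  invisible(NULL)
}
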