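#' Mean absolute error in months
#'
#' `mean(|t_i - y_i|)` over paired targets and predictions.
#'
#' @param targets,predictions Numeric vectors of equal length `>= 1`.
#' @return MAE in the units of the targets (months).
#' @export
mae <- function(targets, predictions) {
  check_pairs(targets, predictions)
  mean(abs(targets - predictions))
}

#' Scaled mean absolute error (percent)
#'
#' `100 * mean(|1 - y_i / t_i|)`: the mean absolute relative error of the
#' predictions, in percent. Requires strictly nonzero targets (ages in
#' months are strictly positive).
#'
#' @param targets,predictions Numeric vectors of equal length `>= 1`.
#' @return SMAE in percent, `>= 0`.
#' @export
smae <- function(targets, predictions) {
  check_pairs(targets, predictions)
  if (any(targets == 0)) stop("smae undefined for zero targets")
  100 * mean(abs(1 - predictions / targets))
}

#' Coefficient of determination
#'
#' Conventional R-squared: `1 - sum((t - y)^2) / sum((t - mean(t))^2)`,
#' with the mean taken over the targets. Equals 1 only for exact
#' predictions; can be negative for models worse than the constant mean.
#'
#' @param targets,predictions Numeric vectors of equal length `>= 2`;
#'   targets must not be constant.
#' @return R-squared, `<= 1`.
#' @export
r_squared <- function(targets, predictions) {
  check_pairs(targets, predictions)
  if (length(targets) < 2L) stop("r_squared requires at least 2 pairs")
  ss_tot <- sum((targets - mean(targets))^2)
  if (ss_tot == 0) stop("r_squared undefined for constant targets")
  1 - sum((targets - predictions)^2) / ss_tot
}

#' Bundle of fit metrics for one set of predictions
#'
#' @param targets,predictions Numeric vectors of equal length.
#' @return A list of class `metrics_report`: `smae_percent`, `mae_months`,
#'   `r_squared` (`NA` when undefined: fewer than 2 pairs or constant
#'   targets), `n`, and `mean_target` (the mean used in the R-squared
#'   denominator).
#' @export
metrics_report <- function(targets, predictions) {
  check_pairs(targets, predictions)
  r2 <- if (length(targets) >= 2L && stats::sd(targets) > 0) {
    r_squared(targets, predictions)
  } else NA_real_
  structure(
    list(smae_percent = smae(targets, predictions),
         mae_months = mae(targets, predictions),
         r_squared = r2, n = length(targets),
         mean_target = mean(targets)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  SMAE = %.4f %%  MAE = %.4f months  R2 = %s\n",
              x$n, x$smae_percent, x$mae_months,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared)))
  invisible(x)
}

check_pairs <- function(targets, predictions) {
  if (length(targets) == 0L) stop("empty input")
  if (length(targets) != length(predictions)) {
    stop("targets and predictions have different lengths")
  }
  if (any(!is.finite(targets)) || any(!is.finite(predictions))) {
    stop("targets and predictions must be finite")
  }
  invisible(NULL)
}
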