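#' Pearson correlation with validation
#'
#' @param x,y Equal-length numeric vectors (length >= 2) with nonzero
#'   variance each.
#' @return Pearson product-moment correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(x, y)
}

#' Mean squared error
#' @param pred,obs Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 1L) stop("need at least 1 observation")
  mean((pred - obs)^2)
}

#' Mean absolute error
#' @param pred,obs Equal-length numeric vectors.
#' @return Mean of absolute differences.
#' @export
mae <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 1L) stop("need at least 1 observation")
  mean(abs(pred - obs))
}

#' Fisher z-test comparing two independent correlations
#'
#' Tests whether two Pearson correlations, estimated on independent samples
#' of sizes `n1` and `n2`, differ. The statistic is
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' referred to the standard normal; the p-value is two-sided.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes, both > 3.
#' @return List with elements `z` and `p` (class `fisher_z`).
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(z = z, p = p, r1 = r1, n1 = n1, r2 = r2, n2 = n2),
            class = "fisher_z")
}

#' @export
print.fisher_z <- function(x, ...) {
  cat(sprintf("Fisher z test: r1=%.3f (n=%d) vs r2=%.3f (n=%d): z = %.3f, p = %.3g\n",
              x$r1, as.integer(x$n1), x$r2, as.integer(x$n2), x$z, x$p))
  invisible(x)
}

#' Correlation between predicted ddG and stability scores
#'
#' Deep-mutational-scan stability scores run opposite to ddG under the
#' convention that positive ddG destabilizes (score < 1 unstable, 1
#' wild-type-like, > 1 more stable). Predictions are therefore sign-flipped
#' before correlating, so that stabilizing predictions align with higher
#' scores; set `destabilizing_positive = FALSE` if the model was trained
#' under the opposite sign convention.
#'
#' @param pred_ddg Predicted ddG values (kcal/mol).
#' @param scores Stability scores, same length.
#' @param destabilizing_positive Sign convention of `pred_ddg`
#'   (default `TRUE`: positive = destabilizing).
#' @return Pearson correlation, with attribute `applied_sign` (-1 or +1)
#'   recording the factor applied to the predictions.
#' @export
stability_score_correlation <- function(pred_ddg, scores,
                                        destabilizing_positive = TRUE) {
  sign_factor <- if (destabilizing_positive) -1 else 1
  r <- pearson(sign_factor * pred_ddg, scores)
  attr(r, "applied_sign") <- sign_factor
  r
}

#' Evaluate predictions against observations
#'
#' @param pred Predicted values.
#' @param obs Observed values, same length (>= 2).
#' @return An `eval_report`: list with `n`, `pcc`, `mse`, `mae`.
#' @export
evaluate_predictions <- function(pred, obs) {
  structure(list(n = length(pred), pcc = pearson(pred, obs),
                 mse = mse(pred, obs), mae = mae(pred, obs)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  PCC=%.3f  MSE=%.3f  MAE=%.3f\n",
              x$n, x$pcc, x$mse, x$mae))
  invisible(x)
}
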