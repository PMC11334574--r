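#' Counting error metrics
#'
#' The three standard counting metrics over a set of N images with
#' true counts C_i and predictions C^_i:
#' MAE = (1/N) sum |C^_i - C_i|,
#' RMSE = sqrt((1/N) sum (C^_i - C_i)^2), and
#' R^2 = 1 - sum (C^_i - C_i)^2 / sum (Cbar - C_i)^2 with Cbar the
#' mean true count.  MAE measures accuracy, RMSE stability (it is
#' never smaller than MAE), and R^2 goodness of fit; R^2 is computed
#' literally and may be negative for predictors worse than the mean.
#'
#' @param preds,trues Equal-length numeric vectors of predicted and
#'   true counts.
#' @return A scalar.
#' @name counting-metrics
NULL

check_pair <- function(preds, trues) {
  if (length(preds) == 0L || length(preds) != length(trues))
    stop("`preds` and `trues` must be nonempty vectors of equal length")
}

#' @rdname counting-metrics
#' @export
count_mae <- function(preds, trues) {
  check_pair(preds, trues)
  mean(abs(preds - trues))
}

#' @rdname counting-metrics
#' @export
count_rmse <- function(preds, trues) {
  check_pair(preds, trues)
  sqrt(mean((preds - trues)^2))
}

#' @rdname counting-metrics
#' @export
count_r2 <- function(preds, trues) {
  check_pair(preds, trues)
  denom <- sum((mean(trues) - trues)^2)
  if (denom == 0)
    stop("R^2 is undefined for constant true counts")
  1 - sum((preds - trues)^2) / denom
}

#' Full metrics report for one evaluation run
#'
#' @inheritParams counting-metrics
#' @return An object of class `metrics_report`: list with `n`,
#'   `mae`, `rmse`, and `r2` (`NA` when the true counts are
#'   constant).
#' @export
metrics_report <- function(preds, trues) {
  check_pair(preds, trues)
  r2 <- if (length(unique(trues)) > 1L) count_r2(preds, trues) else NA_real_
  structure(list(n = length(trues), mae = count_mae(preds, trues),
                 rmse = count_rmse(preds, trues), r2 = r2),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Counting metrics over %d images:\n", x$n))
  cat(sprintf("  MAE  %.2f\n  RMSE %.2f\n", x$mae, x$rmse))
  if (!is.na(x$r2)) cat(sprintf("  R^2  %.2f\n", x$r2))
  if (!is.null(x$strata)) {
    for (nm in names(x$strata)) {
      s <- x$strata[[nm]]
      cat(sprintf("  [%s] n=%d MAE %.2f RMSE %.2f\n", nm, s$n, s$mae,
                  s$rmse))
    }
  }
  invisible(x)
}

#' Density-stratified metrics report
#'
#' Splits the evaluation by scene density (true count at most the
#' threshold vs. greater, default 40) and reports metrics per
#' stratum alongside the pooled values.  An empty stratum is omitted
#' and flagged.
#'
#' @inheritParams counting-metrics
#' @param threshold Density threshold on the true count.
#' @return A `metrics_report` with a `strata` list (`low` = counts
#'   <= threshold, `high` = counts > threshold) and a logical
#'   `omitted` flag vector.
#' @export
stratified_report <- function(preds, trues, threshold = 40) {
  rep <- metrics_report(preds, trues)
  idx <- list(low = trues <= threshold, high = trues > threshold)
  strata <- list()
  omitted <- c(low = FALSE, high = FALSE)
  for (nm in names(idx)) {
    sel <- idx[[nm]]
    if (!any(sel)) { omitted[nm] <- TRUE; next }
    strata[[nm]] <- list(n = sum(sel),
                         mae = count_mae(preds[sel], trues[sel]),
                         rmse = count_rmse(preds[sel], trues[sel]))
  }
  rep$threshold <- threshold
  rep$strata <- strata
  rep$omitted <- omitted
  rep
}

#' Average count per image from dataset totals
#'
#' @param total Total number of annotated objects.
#' @param n Number of images (>= 1).
#' @return `total / n` rounded to 2 decimals, the convention used in
#'   dataset summary tables.
#' @examples
#' mean_count_from_totals(116350, 2738)  # 42.49
#' @export
mean_count_from_totals <- function(total, n) {
  if (n < 1) stop("`n` must be at least 1")
  round(total / n, 2L)
}

#' Relative improvement percentage
#'
#' `100 * (reference - value) / reference`, rounded to 1 decimal:
#' the percentage by which `value` is lower than `reference`, the
#' arithmetic used when comparing model errors.
#'
#' @param reference Baseline (positive) value.
#' @param value Compared value.
#' @return Percentage, 1 decimal.
#' @examples
#' relative_change_pct(3.27, 2.94)  # 10.1
#' @export
relative_change_pct <- function(reference, value) {
  if (reference <= 0) stop("`reference` must be positive")
  round(100 * (reference - value) / reference, 1L)
}
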