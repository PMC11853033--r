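#' ROC curve and trapezoidal AUC for Lmax classification
#'
#' Builds the receiver operating characteristic of the threshold rule over a
#' cohort, taking a cut-off at every distinct Lmax value. Tied values are
#' grouped into a single step, so the trapezoidal area under the curve
#' equals the Mann-Whitney statistic
#' U / (n_pos * n_neg) (concordant pairs plus half the ties).
#'
#' @inheritParams classify_lmax
#' @return An `roc_curve` list: `points` (data.frame `fpr`, `tpr`,
#'   `threshold`; starts at (0,0), ends at (1,1); `threshold` is the Lmax
#'   cut-off generating each operating point, `NA` for the (0,0) sentinel),
#'   `auc`, `direction`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_curve(fixture_lmax_table2())$auc
roc_curve <- function(records, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  records <- validate_cohort(records)
  is_pos <- records$group == "with_lesions"
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop_lum("ROC requires both reference classes")
  # positive calls accumulate from small Lmax under "le", large under "ge"
  score <- if (direction == "le") -records$l_max else records$l_max
  cuts <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) sum(score >= c & is_pos) / n_pos, 0)
  fpr <- vapply(cuts, function(c) sum(score >= c & !is_pos) / n_neg, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(NA_real_, abs(cuts)))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc, direction = direction,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.4f (direction '%s')\n",
              nrow(x$points), x$auc, x$direction))
  invisible(x)
}

#' Plot an ROC curve
#'
#' Draws the curve with the chance diagonal on the active graphics device.
#'
#' @param x an `roc_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}
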