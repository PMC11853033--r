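#' Round half away from zero
#'
#' Display rounding used throughout the report layer (printed tables round
#' 0.005 up, unlike banker's rounding).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a p-value for display
#'
#' Values below the floor print as e.g. `"< 0.001"`; larger values at three
#' decimals.
#'
#' @param p p-value in \[0, 1\].
#' @param floor display floor.
#' @return Character scalar.
#' @export
format_p <- function(p, floor = 0.001) {
  if (is.na(p)) return("NA")
  if (p < floor) sprintf("< %g", floor) else sprintf("= %.3f", p)
}

#' Format diagnostic metrics at report precision
#'
#' Percentages and ratios to two decimals, half-up; undefined ratios print
#' as `"undefined"`.
#'
#' @param metrics a `diagnostic_metrics` object.
#' @return Named character vector.
#' @export
#' @examples
#' format_metrics(diagnostic_metrics(new_contingency(22, 1, 5, 20)))
format_metrics <- function(metrics) {
  stopifnot(inherits(metrics, "diagnostic_metrics"))
  pct <- function(x) if (is.na(x)) "undefined"
                     else sprintf("%.2f%%", round_half_up(100 * x, 2))
  rat <- function(x) if (is.na(x)) "undefined"
                     else sprintf("%.2f", round_half_up(x, 2))
  c(sensitivity = pct(metrics$sensitivity),
    specificity = pct(metrics$specificity),
    `1-sensitivity` = pct(metrics$one_minus_sensitivity),
    `1-specificity` = pct(metrics$one_minus_specificity),
    ppv = pct(metrics$ppv),
    npv = pct(metrics$npv),
    lr_plus = rat(metrics$lr_plus),
    lr_minus = rat(metrics$lr_minus),
    credibility = pct(metrics$credibility))
}

#' Report tables for a threshold sweep
#'
#' `sweep_assignment_table()` lays out the per-threshold contingency counts
#' (with column percentages); `sweep_metrics_table()` lays out the formatted
#' accuracy metrics, one row per threshold.
#'
#' @param sweep a `threshold_sweep`.
#' @return A data.frame.
#' @export
sweep_assignment_table <- function(sweep) {
  stopifnot(inherits(sweep, "threshold_sweep"))
  do.call(rbind, lapply(seq_along(sweep$thresholds), function(i) {
    ct <- sweep$tables[[i]]
    np <- ct$tp + ct$fn; nn <- ct$fp + ct$tn
    data.frame(
      threshold = sweep$thresholds[i],
      test_result = c("positive", "negative"),
      ref_positive_n = c(ct$tp, ct$fn),
      ref_positive_pct = sprintf("%.2f%%", round_half_up(
        100 * c(ct$tp, ct$fn) / np, 2)),
      ref_negative_n = c(ct$fp, ct$tn),
      ref_negative_pct = sprintf("%.2f%%", round_half_up(
        100 * c(ct$fp, ct$tn) / nn, 2)))
  }))
}

#' @rdname sweep_assignment_table
#' @export
sweep_metrics_table <- function(sweep) {
  stopifnot(inherits(sweep, "threshold_sweep"))
  do.call(rbind, lapply(seq_along(sweep$thresholds), function(i) {
    fmt <- format_metrics(sweep$metrics[[i]])
    cbind(data.frame(threshold = sweep$thresholds[i]),
          as.data.frame(as.list(fmt), check.names = FALSE))
  }))
}
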