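#' Classify samples by an Lmax threshold
#'
#' Applies the single-feature decision rule to a cohort: under direction
#' `"le"` a sample is test-positive iff `l_max <= threshold`; under `"ge"`
#' iff `l_max >= threshold`. A sample exactly at the threshold is positive
#' under either direction.
#'
#' Direction `"le"` is the default because it is the only direction
#' consistent with the packaged fixture cohort's published cumulative
#' counts; `"ge"` (lesions brighter, as the luminance characterisation of
#' individual images suggests) remains available for data with that
#' polarity.
#'
#' @param records cohort data.frame (see [read_cohort()]).
#' @param threshold positive Lmax cut-off, cd/m^2.
#' @param direction `"le"` or `"ge"`.
#' @return Logical vector, `TRUE` = test-positive.
#' @export
#' @examples
#' classify_lmax(fixture_lmax_table2(), 1100)
classify_lmax <- function(records, threshold, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  records <- validate_cohort(records)
  if (nrow(records) == 0L) stop_lum("empty cohort")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_lum("'threshold' must be a positive scalar")
  if (direction == "le") records$l_max <= threshold
  else records$l_max >= threshold
}

#' Build a 2x2 contingency table against the reference method
#'
#' Rows are the test result, columns the reference result.
#'
#' @param predictions logical vector, `TRUE` = test-positive.
#' @param reference logical vector (`TRUE` = reference-positive) or the
#'   cohort group labels (`with_lesions` = positive).
#' @return A `contingency_table` list with integer counts `tp`, `fp`, `fn`,
#'   `tn` and `n`.
#' @export
#' @examples
#' fx <- fixture_lmax_table2()
#' contingency_table(classify_lmax(fx, 1100), fx$group)
contingency_table <- function(predictions, reference) {
  if (is.character(reference) || is.factor(reference)) {
    reference <- as.character(reference)
    bad <- setdiff(unique(reference), c("with_lesions", "without_lesions"))
    if (length(bad) > 0)
      stop_lum("unknown reference label(s): ", paste(bad, collapse = ", "))
    reference <- reference == "with_lesions"
  }
  if (!is.logical(predictions) || !is.logical(reference))
    stop_lum("'predictions' and 'reference' must be logical (or group labels)")
  if (length(predictions) != length(reference))
    stop_lum("'predictions' and 'reference' differ in length")
  if (anyNA(predictions) || anyNA(reference)) stop_lum("NA in inputs")
  new_contingency(tp = sum(predictions & reference),
                  fp = sum(predictions & !reference),
                  fn = sum(!predictions & reference),
                  tn = sum(!predictions & !reference))
}

#' @param tp,fp,fn,tn cell counts (test result in rows, reference in columns).
#' @rdname contingency_table
#' @export
new_contingency <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  cells <- as.integer(cells)
  if (anyNA(cells) || any(cells < 0L)) stop_lum("counts must be >= 0")
  n <- sum(cells)
  if (n < 1L) stop_lum("contingency table must contain at least one sample")
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4],
                 n = n),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  cat("<contingency_table>\n")
  print(m)
  invisible(x)
}

as_matrix_ct <- function(x)
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2)

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, their
#' complements, predictive values `ppv = tp/(tp+fp)` and `npv = tn/(tn+fn)`,
#' likelihood ratios `lr_plus = sens/(1-spec)` and
#' `lr_minus = (1-sens)/spec`, and `credibility` — overall agreement with
#' the reference, `(tp+tn)/n`. Proportions are returned on the 0-1 scale at
#' full precision; see [format_metrics()] for display rounding.
#'
#' Ratios with a zero denominator (e.g. LR+ for a perfectly specific test)
#' are reported as `NA`, an explicit "undefined" marker.
#'
#' @param table a `contingency_table`.
#' @return A `diagnostic_metrics` list.
#' @export
#' @examples
#' m <- diagnostic_metrics(new_contingency(22, 1, 5, 20))
#' round(100 * m$sensitivity, 2)  # 81.48
diagnostic_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$tp + table$fn < 1L || table$fp + table$tn < 1L)
    stop_lum("reference must contain at least one positive and one negative")
  sens <- table$tp / (table$tp + table$fn)
  spec <- table$tn / (table$fp + table$tn)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    sensitivity = sens,
    specificity = spec,
    one_minus_sensitivity = 1 - sens,
    one_minus_specificity = 1 - spec,
    ppv = safe_div(table$tp, table$tp + table$fp),
    npv = safe_div(table$tn, table$tn + table$fn),
    lr_plus = safe_div(sens, 1 - spec),
    lr_minus = safe_div(1 - sens, spec),
    credibility = (table$tp + table$tn) / table$n),
    class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- format_metrics(x)
  cat("<diagnostic_metrics>\n")
  for (k in names(fmt)) cat(sprintf("  %-22s %s\n", k, fmt[[k]]))
  invisible(x)
}

#' Sweep classification thresholds over a cohort
#'
#' Evaluates the threshold rule at each grid value, returning the 2x2 table
#' and the full metric set per threshold. Positive-call counts are
#' non-decreasing in the threshold under direction `"le"` and non-increasing
#' under `"ge"` (a structural invariant of nested decision rules, asserted
#' internally). The sweep additionally warns when the best Youden J over the
#' grid is negative — the signature of a rule whose polarity does not match
#' the data.
#'
#' @inheritParams classify_lmax
#' @param thresholds numeric grid of cut-offs, cd/m^2.
#' @return A `threshold_sweep` list: `thresholds`, `direction`, `tables`
#'   (list of `contingency_table`), `metrics` (list of
#'   `diagnostic_metrics`), and `summary` (one data.frame row per
#'   threshold).
#' @export
#' @examples
#' sw <- sweep_thresholds(fixture_lmax_table2(), table2_thresholds())
#' sw$summary[, c("threshold", "tp", "fp", "sensitivity", "specificity")]
sweep_thresholds <- function(records, thresholds = table2_thresholds(),
                             direction = c("le", "ge")) {
  direction <- match.arg(direction)
  records <- validate_cohort(records)
  if (length(thresholds) < 1L) stop_lum("empty threshold grid")
  tables <- lapply(thresholds, function(t)
    contingency_table(classify_lmax(records, t, direction), records$group))
  metrics <- lapply(tables, diagnostic_metrics)
  summary <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    ct <- tables[[i]]; m <- metrics[[i]]
    data.frame(threshold = thresholds[i], tp = ct$tp, fp = ct$fp,
               fn = ct$fn, tn = ct$tn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, lr_plus = m$lr_plus,
               lr_minus = m$lr_minus, credibility = m$credibility)
  }))
  # structural invariant: positive calls are nested across thresholds
  pos <- summary$tp + summary$fp
  ord <- order(summary$threshold)
  monotone <- if (direction == "le") !is.unsorted(pos[ord])
              else !is.unsorted(rev(pos[ord]))
  stopifnot(monotone)
  # polarity diagnostic: a rule pointing the wrong way never beats chance
  polarity_ok <- max(summary$sensitivity + summary$specificity - 1) >= 0
  if (!polarity_ok)
    warning("best Youden J is negative under direction '", direction,
            "': the rule polarity appears inverted for this cohort",
            call. = FALSE)
  structure(list(thresholds = thresholds, direction = direction,
                 tables = tables, metrics = metrics, summary = summary,
                 monotone = monotone, polarity_ok = polarity_ok),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %d thresholds, direction '%s'\n",
              length(x$thresholds), x$direction))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Select the operating threshold from a sweep
#'
#' Picks the grid threshold maximising Youden's J = sensitivity +
#' specificity - 1. Exact ties are broken toward the largest threshold; all
#' tied thresholds are reported in the rationale.
#'
#' @param sweep a `threshold_sweep`.
#' @param tol tie tolerance on J.
#' @return A list: `threshold` (the selection), `youden_j`, `tied` (all
#'   thresholds achieving the maximum), `rationale` (text).
#' @export
#' @examples
#' select_threshold(sweep_thresholds(fixture_lmax_table2()))
select_threshold <- function(sweep, tol = 1e-9) {
  stopifnot(inherits(sweep, "threshold_sweep"))
  j <- sweep$summary$sensitivity + sweep$summary$specificity - 1
  best <- max(j)
  tied <- sort(sweep$summary$threshold[j >= best - tol])
  chosen <- max(tied)
  list(threshold = chosen, youden_j = best, tied = tied,
       rationale = sprintf(
         "max Youden J = %.4f at threshold%s %s cd/m^2; selected %g (largest)",
         best, if (length(tied) > 1) "s" else "",
         paste(tied, collapse = ", "), chosen))
}
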