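#' Pearson chi-squared test and Cramer's V for a 2x2 table
#'
#' Computes the chi-squared statistic from the observed cell counts and the
#' margin-derived expected counts, `sum((O - E)^2 / E)`, with 1 degree of
#' freedom, and the association strength Cramer's
#' `V = sqrt(chi2 / (n * min(k - 1, r - 1)))` (= `sqrt(chi2 / n)` for 2x2).
#' No continuity correction is applied by default; the uncorrected statistic
#' is the definitional formula. Yates' correction is available behind
#' `correction = "yates"`.
#'
#' @param table a `contingency_table` (see [contingency_table()]).
#' @param correction `"none"` (default) or `"yates"`.
#' @return An `association_result` list: `chi2`, `df` (= 1), `p_value`
#'   (upper tail, 1 df), `cramers_v`, `correction`.
#' @export
#' @examples
#' a <- chi_square_2x2(new_contingency(22, 1, 5, 20))
#' round(a$chi2, 2)       # 27.86
#' round(a$cramers_v, 2)  # 0.76
chi_square_2x2 <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  stopifnot(inherits(table, "contingency_table"))
  O <- as_matrix_ct(table)
  rs <- rowSums(O); cs <- colSums(O); n <- sum(O)
  if (any(rs == 0) || any(cs == 0))
    stop_lum("chi-squared undefined: a table margin is zero")
  E <- outer(rs, cs) / n
  dev <- abs(O - E)
  if (correction == "yates") dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  v <- sqrt(chi2 / n)  # min(k-1, r-1) = 1 for a 2x2 table
  structure(list(chi2 = chi2, df = 1L,
                 p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
                 cramers_v = v, correction = correction),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> chi2(%d) = %.4f, p %s, Cramer's V = %.4f%s\n",
              x$df, x$chi2, format_p(x$p_value), x$cramers_v,
              if (x$correction == "yates") " (Yates-corrected)" else ""))
  invisible(x)
}

#' Rank-based comparison of Lmax between the two reference groups
#'
#' Two-sample rank-sum (Mann-Whitney) comparison under the normal
#' approximation with tie correction. The Z statistic is signed: positive
#' when the `with_lesions` group tends to have larger Lmax. The effect size
#' is the rank-biserial-style correlation `r = Z / sqrt(n)`.
#'
#' @param records cohort data.frame (see [read_cohort()]).
#' @return A list: `z`, `p_value` (two-sided), `r`, `u` (Mann-Whitney U of
#'   the `with_lesions` group), `n_pos`, `n_neg`.
#' @export
#' @examples
#' rank_group_comparison(fixture_lmax_table2())
rank_group_comparison <- function(records) {
  records <- validate_cohort(records)
  pos <- records$l_max[records$group == "with_lesions"]
  neg <- records$l_max[records$group == "without_lesions"]
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0L || n2 == 0L) stop_lum("both reference groups must be present")
  x <- c(pos, neg)
  n <- n1 + n2
  rk <- rank(x)
  r1 <- sum(rk[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  list(z = z, p_value = 2 * pnorm(-abs(z)), r = z / sqrt(n),
       u = u, n_pos = n1, n_neg = n2)
}

# Hanley-McNeil variance of the empirical AUC estimate.
auc_variance_hm <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
     (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Minimum sample size for distinguishing an ROC AUC from chance
#'
#' Hanley-McNeil-style calculation: the smallest total n such that a
#' one-sided level-`alpha` test of AUC = 0.5 has power `1 - beta` against
#' the alternative `auc_alt`, with the negative group sized
#' `ceiling(neg_pos_ratio * n_pos)`. Found by direct search over `n_pos`.
#'
#' @param alpha one-sided type-I error, in (0, 1).
#' @param beta type-II error, in (0, 1).
#' @param neg_pos_ratio ratio of negative to positive samples (> 0).
#' @param auc_alt alternative AUC, in (0.5, 1). There is no default: the
#'   assumed alternative must be stated explicitly.
#' @param max_n_pos search cap.
#' @return A list: `n_total`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' sample_size_auc(0.01, 0.01, 0.7, auc_alt = 0.8)
sample_size_auc <- function(alpha, beta, neg_pos_ratio, auc_alt,
                            max_n_pos = 100000L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1 ||
      !is.numeric(beta) || beta <= 0 || beta >= 1)
    stop_lum("'alpha' and 'beta' must be in (0, 1)")
  if (!is.numeric(neg_pos_ratio) || neg_pos_ratio <= 0)
    stop_lum("'neg_pos_ratio' must be > 0")
  if (!is.numeric(auc_alt) || auc_alt <= 0.5 || auc_alt >= 1)
    stop_lum("'auc_alt' must be in (0.5, 1)")
  za <- qnorm(1 - alpha); zb <- qnorm(1 - beta)
  for (n_pos in seq_len(max_n_pos)) {
    n_neg <- max(1L, as.integer(ceiling(neg_pos_ratio * n_pos)))
    v0 <- auc_variance_hm(0.5, n_pos, n_neg)
    v1 <- auc_variance_hm(auc_alt, n_pos, n_neg)
    if (auc_alt - 0.5 >= za * sqrt(v0) + zb * sqrt(v1))
      return(list(n_total = n_pos + n_neg, n_pos = n_pos, n_neg = n_neg))
  }
  stop_lum("no sample size found below the search cap")
}
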