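#' Simulate a cohort of per-sample maximum luminance values
#'
#' Draws Lmax values for a reference-positive group (`with_lesions`) and a
#' reference-negative group (`without_lesions`) from parametric
#' location/scale families, as a stand-in for a bench-measured cohort.
#'
#' @param n_pos,n_neg group sizes (>= 1).
#' @param pos_dist,neg_dist distribution descriptors:
#'   `list(family, mean, sd)` with family `"normal"` (Gaussian, redrawn if a
#'   draw is <= 0) or `"uniform"` (`mean` +/- `sd * sqrt(3)`). `sd = 0`
#'   yields a degenerate (constant) distribution.
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return A data.frame with columns `sample_id`, `group`
#'   (`with_lesions` / `without_lesions`) and `l_max` (cd/m^2).
#' @export
#' @examples
#' coh <- generate_cohort(27, 21, seed = 7)
#' table(coh$group)
generate_cohort <- function(n_pos, n_neg,
                            pos_dist = list(family = "normal",
                                            mean = 1075, sd = 45),
                            neg_dist = list(family = "normal",
                                            mean = 1150, sd = 45),
                            seed = 1L) {
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  if (is.na(n_pos) || is.na(n_neg) || n_pos < 1L || n_neg < 1L)
    stop_lum("'n_pos' and 'n_neg' must be >= 1")
  draw <- function(n, d) {
    if (!is.list(d) || is.null(d$mean) || is.null(d$sd) ||
        !is.finite(d$mean) || !is.finite(d$sd) || d$sd < 0)
      stop_lum("distribution must be list(family, mean, sd) with sd >= 0")
    family <- if (is.null(d$family)) "normal" else d$family
    switch(family,
      normal = {
        x <- rnorm(n, d$mean, d$sd)
        while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), d$mean, d$sd)
        x
      },
      uniform = runif(n, d$mean - d$sd * sqrt(3), d$mean + d$sd * sqrt(3)),
      stop_lum("unknown distribution family: ", family))
  }
  with_seed(seed, {
    pos <- draw(n_pos, pos_dist)
    neg <- draw(n_neg, neg_dist)
    data.frame(
      sample_id = c(sprintf("L%02d", seq_len(n_pos)),
                    sprintf("H%02d", seq_len(n_neg))),
      group = rep(c("with_lesions", "without_lesions"), c(n_pos, n_neg)),
      l_max = c(pos, neg),
      stringsAsFactors = FALSE)
  })
}

# Representative Lmax value per cumulative-count bin. Bins are closed on the
# right, matching the positive-iff-Lmax<=t classification rule; values are
# bin midpoints, with bound -/+ 20 for the two open end bins. Downstream
# counts depend only on bin membership, never on these representatives.
.fixture_bins <- list(
  with_lesions = data.frame(
    l_max = c(1050, 1075, 1085, 1150),
    n = c(18L, 2L, 2L, 5L)),
  without_lesions = data.frame(
    l_max = c(1050, 1105, 1115, 1125, 1150),
    n = c(1L, 3L, 2L, 1L, 14L)))

#' Packaged 48-sample Lmax fixture cohort
#'
#' A fixed cohort of 27 reference-positive and 21 reference-negative samples
#' whose Lmax values are reconstructed from published cumulative
#' threshold-assignment counts: under the rule "positive iff Lmax <= t"
#' evaluated at t in 1070, 1080, ..., 1130 cd/m^2 it reproduces every
#' published contingency count. Per-sample Lmax values were never published;
#' the representatives here are bin midpoints (open bins: bound -/+ 20 cd/m^2),
#' so only bin membership — not the exact values — is meaningful. The cohort
#' is synthetic in that sense.
#'
#' @return A data.frame with columns `sample_id`, `group`, `l_max`
#'   (48 rows, 27 `with_lesions`).
#' @seealso [sweep_thresholds()], [table2_thresholds()]
#' @export
#' @examples
#' fx <- fixture_lmax_table2()
#' table(fx$group)
fixture_lmax_table2 <- function() {
  rec <- lapply(names(.fixture_bins), function(g) {
    b <- .fixture_bins[[g]]
    data.frame(group = g, l_max = rep(b$l_max, b$n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  prefix <- c(with_lesions = "L", without_lesions = "H")[out$group]
  out$sample_id <- paste0(prefix, sprintf("%02d", stats::ave(
    seq_len(nrow(out)), out$group, FUN = seq_along)))
  out[, c("sample_id", "group", "l_max")]
}

#' Canonical threshold grid for the fixture cohort
#'
#' The seven Lmax cut-off levels (cd/m^2) at which the fixture cohort's
#' contingency tables are defined.
#'
#' @return Numeric vector `c(1070, 1080, ..., 1130)`.
#' @export
table2_thresholds <- function() seq(1070, 1130, by = 10)

#' Read / write a cohort CSV
#'
#' Cohort files are plain CSV with header `sample_id,group,l_max`; `group`
#' must be `with_lesions` or `without_lesions` and `l_max` positive.
#'
#' @param path file path.
#' @return `read_cohort()`: the validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_lum("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @param cohort a cohort data.frame (`sample_id`, `group`, `l_max`).
#' @rdname read_cohort
#' @return `write_cohort()`: `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_cohort <- function(df) {
  need <- c("sample_id", "group", "l_max")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop_lum("cohort must have columns sample_id, group, l_max")
  df$l_max <- as.numeric(df$l_max)
  if (anyNA(df$l_max) || any(df$l_max <= 0))
    stop_lum("'l_max' must be positive and numeric")
  bad <- setdiff(unique(df$group), c("with_lesions", "without_lesions"))
  if (length(bad) > 0)
    stop_lum("unknown group label(s): ", paste(bad, collapse = ", "))
  df[, need]
}
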