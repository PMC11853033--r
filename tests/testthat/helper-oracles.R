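# Independent oracles and fixture builders used across the suite.

# Brute-force flood-fill connected-component labelling (queue-based, scalar).
# Deliberately naive and independent of the package's graph-based labelling.
flood_label <- function(sel, connectivity = 8) {
  nr <- nrow(sel); nc <- ncol(sel)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (sel[r, cc] && lab[r, cc] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, cc)); lab[r, cc] <- cur
      while (length(queue) > 0L) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (o in offs) {
          rr <- p[1] + o[1]; c2 <- p[2] + o[2]
          if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
              sel[rr, c2] && lab[rr, c2] == 0L) {
            lab[rr, c2] <- cur
            queue[[length(queue) + 1L]] <- c(rr, c2)
          }
        }
      }
    }
  }
  lab
}

# Canonical representation of a pixel partition: list of sorted linear-index
# vectors, ordered by their smallest member.
canonical_partition <- function(groups) {
  groups <- lapply(groups, function(g) unname(sort(g)))
  unname(groups[order(vapply(groups, min, 0))])
}

foci_partition <- function(foci, nr) {
  canonical_partition(lapply(foci, function(f)
    f$pixel_indices[, "row"] + (f$pixel_indices[, "col"] - 1L) * nr))
}

flood_partition <- function(sel, connectivity) {
  lab <- flood_label(sel, connectivity)
  canonical_partition(split(which(sel), lab[sel]))
}

# Pairwise Mann-Whitney AUC: concordant pairs + half ties, enumerated.
pairwise_auc <- function(score_pos, score_neg) {
  total <- 0
  for (p in score_pos) for (n in score_neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(score_pos) * length(score_neg))
}

# A small map with known band structure: n_lesion pixels at lesion_level on
# a base-level background, in a deterministic scattered layout.
mixed_map <- function(nr = 10, nc = 10, n_lesion = 30, base = 500,
                      lesion_level = 900, seed = 42) {
  v <- matrix(base, nr, nc)
  idx <- withr::with_seed(seed, sample(nr * nc, n_lesion))
  v[idx] <- lesion_level
  luminance_map(v)
}

# Published per-threshold accuracy values (percentages / ratios as printed,
# two decimals): threshold, sens, spec, 1-sens, 1-spec, ppv, npv, lr+, lr-,
# credibility.
published_metrics <- data.frame(
  threshold = seq(1070, 1130, 10),
  sensitivity = c(66.67, 74.07, 81.48, 81.48, 81.48, 81.48, 81.48),
  specificity = c(95.24, 95.24, 95.24, 95.24, 80.95, 71.43, 66.67),
  one_minus_sensitivity = c(33.33, 25.93, 18.52, 18.52, 18.52, 18.52, 18.52),
  one_minus_specificity = c(4.76, 4.76, 4.76, 4.76, 19.05, 28.57, 33.33),
  ppv = c(94.74, 95.24, 95.65, 95.65, 84.62, 78.57, 75.86),
  npv = c(68.97, 74.07, 80.00, 80.00, 77.27, 75.00, 73.68),
  lr_plus = c(14.00, 15.56, 17.11, 17.11, 4.28, 2.85, 2.44),
  lr_minus = c(0.35, 0.27, 0.19, 0.19, 0.23, 0.26, 0.28),
  credibility = c(79.17, 83.33, 87.50, 87.50, 81.25, 77.08, 75.00))

# Published per-threshold contingency counts: tp, fp, fn, tn.
published_counts <- data.frame(
  threshold = seq(1070, 1130, 10),
  tp = c(18, 20, 22, 22, 22, 22, 22),
  fp = c(1, 1, 1, 1, 4, 6, 7),
  fn = c(9, 7, 5, 5, 5, 5, 5),
  tn = c(20, 20, 20, 20, 17, 15, 14))

python_bin <- function() Sys.which("python")
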