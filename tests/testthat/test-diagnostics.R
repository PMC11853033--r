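test_that("threshold classification follows the rule and boundary convention", {
  rec <- data.frame(sample_id = c("a", "b"),
                    group = c("with_lesions", "without_lesions"),
                    l_max = c(1090, 1110))
  expect_equal(classify_lmax(rec, 1100, "le"), c(TRUE, FALSE))
  expect_equal(classify_lmax(rec, 1100, "ge"), c(FALSE, TRUE))

  at <- data.frame(sample_id = "x", group = "with_lesions", l_max = 1100)
  expect_true(classify_lmax(at, 1100, "le"))
  expect_true(classify_lmax(at, 1100, "ge"))

  fx <- fixture_lmax_table2()
  expect_equal(sum(classify_lmax(fx, 1100, "le")), 23)  # 22 TP + 1 FP
  expect_error(classify_lmax(fx, -1), "positive")
})

test_that("contingency tables count agreement with the reference", {
  perfect <- contingency_table(rep(c(TRUE, FALSE), c(5, 5)),
                               rep(c(TRUE, FALSE), c(5, 5)))
  expect_equal(unlist(perfect[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(5, 0, 0, 5))
  allpos <- contingency_table(rep(TRUE, 48),
                              rep(c("with_lesions", "without_lesions"),
                                  c(27, 21)))
  expect_equal(unlist(allpos[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(27, 21, 0, 0))
  fx <- fixture_lmax_table2()
  ct <- contingency_table(classify_lmax(fx, 1100), fx$group)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(22, 1, 5, 20))
  expect_error(contingency_table(TRUE, c(TRUE, FALSE)), "length")
  expect_error(contingency_table(c(TRUE, TRUE), c("with_lesions", "cancer")),
               "unknown")
  expect_error(new_contingency(0, 0, 0, 0), "at least one")
})

test_that("diagnostic metrics reproduce the published accuracy rows", {
  m1100 <- format_metrics(diagnostic_metrics(new_contingency(22, 1, 5, 20)))
  expect_equal(unname(m1100[c("sensitivity", "specificity", "ppv", "npv",
                              "lr_plus", "lr_minus", "credibility")]),
               c("81.48%", "95.24%", "95.65%", "80.00%", "17.11", "0.19",
                 "87.50%"))
  m1070 <- format_metrics(diagnostic_metrics(new_contingency(18, 1, 9, 20)))
  expect_equal(unname(m1070[c("sensitivity", "ppv", "npv", "lr_plus",
                              "credibility")]),
               c("66.67%", "94.74%", "68.97%", "14.00", "79.17%"))
})

test_that("perfect tests report undefined LR+ and complements sum to one", {
  m <- diagnostic_metrics(new_contingency(10, 0, 0, 10))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_true(is.na(m$lr_plus))
  expect_equal(m$lr_minus, 0)
  expect_equal(m$credibility, 1)
  expect_equal(format_metrics(m)[["lr_plus"]], "undefined")

  r <- diagnostic_metrics(new_contingency(13, 4, 7, 9))
  expect_equal(r$sensitivity + r$one_minus_sensitivity, 1)
  expect_equal(r$specificity + r$one_minus_specificity, 1)
  expect_equal(r$lr_plus, r$sensitivity / (1 - r$specificity))
  expect_equal(r$lr_minus, (1 - r$sensitivity) / r$specificity)
  expect_true((r$lr_plus >= 1) == (r$sensitivity + r$specificity >= 1))

  expect_error(diagnostic_metrics(new_contingency(0, 3, 0, 4)),
               "at least one positive")
})

test_that("published counts are only consistent with the 'le' polarity", {
  fx <- fixture_lmax_table2()
  sw <- sweep_thresholds(fx, table2_thresholds(), "le")
  pos <- sw$summary$tp + sw$summary$fp
  expect_false(is.unsorted(pos))
  expect_true(sw$polarity_ok)

  # the published positive counts strictly increase with the threshold, so
  # they cannot have been produced by a >=-threshold rule (whose positive
  # calls shrink as the threshold rises); regression-tested as documentation
  published_pos <- published_counts$tp + published_counts$fp
  expect_true(any(diff(published_pos) > 0))

  # sweeping the fixture under "ge" yields worse-than-chance accuracy at
  # every threshold, and the sweep flags the inverted polarity
  expect_warning(sw_ge <- sweep_thresholds(fx, table2_thresholds(), "ge"),
                 "polarity")
  expect_false(sw_ge$polarity_ok)
  pos_ge <- sw_ge$summary$tp + sw_ge$summary$fp
  expect_false(is.unsorted(rev(pos_ge)))
  expect_false(identical(sw_ge$summary$tp, published_counts$tp))

  expect_error(sweep_thresholds(fx, numeric(0)), "empty")
  one_class <- data.frame(sample_id = "a", group = "with_lesions",
                          l_max = 1000)
  expect_error(sweep_thresholds(one_class, 1100), "at least one")
})

test_that("threshold selection maximises Youden's J with ties to the larger", {
  sel <- select_threshold(sweep_thresholds(fixture_lmax_table2()))
  expect_equal(sel$threshold, 1100)
  expect_equal(sel$tied, c(1090, 1100))
  expect_match(sel$rationale, "1090, 1100")

  coh <- generate_cohort(6, 6,
                         pos_dist = list(mean = 1000, sd = 0),
                         neg_dist = list(mean = 1200, sd = 0), seed = 1)
  sep <- select_threshold(sweep_thresholds(coh, c(1050, 1100, 1150)))
  expect_equal(sep$youden_j, 1)
  single <- select_threshold(sweep_thresholds(coh, 1100))
  expect_equal(single$threshold, 1100)
})

test_that("chi-squared matches the published statistic and a formula oracle", {
  a <- chi_square_2x2(new_contingency(22, 1, 5, 20))
  expect_equal(round(a$chi2, 2), 27.86)
  expect_equal(round(a$cramers_v, 2), 0.76)
  expect_lt(a$p_value, 0.001)
  expect_equal(a$df, 1L)

  # independence: identical row proportions
  z <- chi_square_2x2(new_contingency(10, 10, 10, 10))
  expect_equal(z$chi2, 0)
  expect_equal(z$cramers_v, 0)

  # oracle: base-R chisq.test without correction, on random tables
  for (seed in 1:8) {
    cells <- withr::with_seed(seed, sample(0:30, 4, replace = TRUE))
    if (sum(cells) == 0) cells <- cells + 1
    tab <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- chi_square_2x2(new_contingency(cells[1], cells[2], cells[3],
                                          cells[4]))
    want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$chi2, unname(want$statistic))
    expect_equal(got$p_value, want$p.value)
    expect_equal(got$cramers_v, sqrt(got$chi2 / sum(cells)))
  }
})

test_that("chi-squared is invariant to simultaneous row/column permutation", {
  a <- chi_square_2x2(new_contingency(22, 1, 5, 20))
  flipped <- chi_square_2x2(new_contingency(20, 5, 1, 22))  # swap both axes
  expect_equal(a$chi2, flipped$chi2)
  expect_equal(a$cramers_v, flipped$cramers_v)
})

test_that("Yates correction is available and reduces the statistic", {
  plain <- chi_square_2x2(new_contingency(22, 1, 5, 20))
  yates <- chi_square_2x2(new_contingency(22, 1, 5, 20), correction = "yates")
  expect_lt(yates$chi2, plain$chi2)
  expect_false(round(yates$chi2, 2) == 27.86)
  expect_error(chi_square_2x2(new_contingency(3, 4, 0, 0)), "margin")
})

test_that("rank comparison matches the rank-sum oracle and wilcox.test", {
  same <- data.frame(sample_id = letters[1:6],
                     group = rep(c("with_lesions", "without_lesions"), 3),
                     l_max = rep(7, 6))
  r0 <- rank_group_comparison(same)
  expect_equal(r0$z, 0)
  expect_equal(r0$r, 0)

  # fully separated groups of 27 and 21: |Z| at its closed-form maximum
  sep <- data.frame(
    sample_id = sprintf("s%02d", 1:48),
    group = rep(c("with_lesions", "without_lesions"), c(27, 21)),
    l_max = c(seq(2000, by = 1, length.out = 27),
              seq(100, by = 1, length.out = 21)))
  rs <- rank_group_comparison(sep)
  u_max <- 27 * 21
  sigma <- sqrt(27 * 21 * (48 + 1) / 12)
  expect_equal(rs$z, (u_max - u_max / 2) / sigma)
  expect_equal(rs$u, u_max)

  # p-value oracle: wilcox.test normal approximation with tie correction
  for (seed in 1:6) {
    coh <- generate_cohort(9, 7, seed = seed)
    got <- rank_group_comparison(coh)
    want <- suppressWarnings(stats::wilcox.test(
      l_max ~ group, data = coh, exact = FALSE, correct = FALSE))
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
    expect_equal(got$r, got$z / sqrt(16))
  }
  expect_error(rank_group_comparison(same[same$group == "with_lesions", ]),
               "both reference groups")
})

test_that("sample size search agrees with an independent scan of the power", {
  # independent oracle: recompute the inequality over a dense n grid
  oracle <- function(alpha, beta, ratio, auc) {
    hm <- function(a, np, nn) {
      q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
      (a * (1 - a) + (np - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) / (np * nn)
    }
    for (np in 1:5000) {
      nn <- max(1, ceiling(ratio * np))
      ok <- (auc - 0.5) >= qnorm(1 - alpha) * sqrt(hm(0.5, np, nn)) +
        qnorm(1 - beta) * sqrt(hm(auc, np, nn))
      if (ok) return(np + nn)
    }
    NA
  }
  for (case in list(c(0.01, 0.01, 0.7, 0.8), c(0.05, 0.2, 1, 0.75),
                    c(0.05, 0.1, 2, 0.9))) {
    got <- sample_size_auc(case[1], case[2], case[3], case[4])
    expect_equal(got$n_total, oracle(case[1], case[2], case[3], case[4]))
    expect_equal(got$n_neg, max(1, ceiling(case[3] * got$n_pos)))
  }

  # degenerate errors: both z-quantiles zero, minimal n
  tiny <- sample_size_auc(0.5, 0.5, 0.7, 0.8)
  expect_equal(tiny$n_pos, 1)

  # a stronger alternative AUC never needs more samples
  sizes <- vapply(c(0.7, 0.8, 0.9, 0.95), function(a)
    sample_size_auc(0.01, 0.01, 0.7, a)$n_total, 0)
  expect_false(is.unsorted(rev(sizes)))
  expect_error(sample_size_auc(0.01, 0.01, 0.7, 0.4), "auc_alt")
  expect_error(sample_size_auc(1.2, 0.01, 0.7, 0.8), "alpha")
})
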