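test_that("AUC matches hand counts and handles degenerate scores", {
  r <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(r$auc, 0.75)                       # 3 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 1, 0), c(5, 4, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  # curve endpoints
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
})

test_that("AUC equals brute-force pairwise ranking on random cohorts", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # many ties
    expect_equal(roc_auc(labels, scores)$auc, brute_auc(labels, scores))
  }
})

test_that("sensitivity/specificity at the alpha cutoff", {
  perfect <- sens_spec_at_cutoff(c(TRUE, FALSE), c(55, 70))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  # 2x2 oracle: TP = 8, FN = 2, TN = 9, FP = 1
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  alpha <- c(rep(55, 8), rep(65, 2), rep(70, 9), rep(50, 1))
  ss <- sens_spec_at_cutoff(truth, alpha)
  expect_equal(ss$sensitivity, 0.8)
  expect_equal(ss$specificity, 0.9)
  expect_identical(unname(ss$table["ddh", "ddh"]), 8L)
  expect_error(sens_spec_at_cutoff(rep(FALSE, 5), rep(70, 5)), "no positive")
  expect_error(sens_spec_at_cutoff(rep(TRUE, 5), rep(50, 5)), "no negative")
})

test_that("pooled t test matches the closed form and stats::t.test", {
  a <- c(2.1, 2.5, 2.3, 2.7); b <- c(3.1, 3.3, 2.9, 3.5)
  got <- student_t_test(a, b)
  expect_equal(got$t, brute_pooled_t(a, b), tolerance = 1e-9)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter))

  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- student_t_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 0.01)
  # symmetry: swapping groups negates t, preserves p
  sw <- student_t_test(b, a)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$p, got$p)
  # Welch variant agrees with stats::t.test default
  w <- student_t_test(a, c(b, 10), welch = TRUE)
  rw <- stats::t.test(a, c(b, 10))
  expect_equal(w$t, unname(rw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(rw$parameter), tolerance = 1e-9)
  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment matches brute force and is order invariant", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 4)), rep(1, 4))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (rep in 1:10) {
    p <- round(runif(sample(3:20, 1)), 3)
    expect_equal(fdr_adjust(p), brute_bh(p))
    expect_equal(fdr_adjust(p), stats::p.adjust(p, "BH"))
    o <- sample(seq_along(p))
    expect_equal(fdr_adjust(p[o]), fdr_adjust(p)[o])
  }
})

test_that("per-frame rater errors are the stated spreads", {
  m <- rbind(c(60, 62), c(65, 65))
  re <- rater_errors(m)
  expect_equal(re$inter, abs(61 - 65))
  expect_equal(re$intra, mean(c(2, 0)))
})

test_that("rater comparison separates quality groups and needs both", {
  set.seed(41)
  qualified <- rep(c(TRUE, FALSE), each = 100)
  ms <- lapply(qualified, function(q)
    simulate_rater_alphas(60, q, sd_qualified = 1, sd_disqualified = 4))
  cmp <- rater_error_comparison(qualified, ms)
  expect_lt(cmp$inter$mean_qualified, cmp$inter$mean_disqualified)
  expect_lt(cmp$intra$mean_qualified, cmp$intra$mean_disqualified)
  expect_lt(cmp$inter$p, 0.05)
  expect_lt(cmp$intra$p, 0.05)
  expect_error(rater_error_comparison(logical(), list()), "per frame")
  expect_error(rater_error_comparison(rep(TRUE, 3), ms[1:3]), "both")
})
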