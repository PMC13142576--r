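# Two-group comparison statistics.

test_that("pooled_t matches hand arithmetic and printed cohort values", {
  # identical summaries
  expect_equal(pooled_t(5, 1, 10, 5, 1, 10)$t, 0)
  # 3-vs-3 toy with hand-computed pooled SD:
  # group1 {1,2,3}: m=2, s^2=1; group2 {4,6,8}: m=6, s^2=4
  # sp^2 = (2*1 + 2*4)/4 = 2.5; t = -4 / (sqrt(2.5)*sqrt(2/3))
  h <- pooled_t(2, 1, 3, 6, 2, 3)
  expect_equal(h$t, -4 / (sqrt(2.5) * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(h$df, 4)
  # mean composite, non-converters vs converters (340 vs 100)
  r <- pooled_t(48.53, 6.22, 340, 45.66, 6.28, 100)
  expect_lt(abs(r$t - 4.04), 0.01)
})

test_that("welch_t matches printed cohort value and reduces to pooled", {
  expect_equal(welch_t(5, 1, 8, 5, 2, 9)$t, 0)
  # age, controls vs Stage 2
  expect_lt(abs(welch_t(64.64, 12.11, 102, 67.77, 6.39, 832)$t - (-2.56)),
            0.01)
  # equal variances and equal n: algebraically identical to pooled t
  set.seed(42)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1); s <- runif(1, 0.5, 3); n <- sample(5:50, 1)
    expect_equal(welch_t(m1, s, n, m2, s, n)$t,
                 pooled_t(m1, s, n, m2, s, n)$t, tolerance = 1e-12)
    expect_equal(welch_t(m1, s, n, m2, s, n)$df, 2 * n - 2, tolerance = 1e-9)
  }
})

test_that("variance F test matches the F distribution and is monotone", {
  expect_equal(variance_f_test(1, 10, 1, 10), 1)
  # s1^2 = 4 vs s2^2 = 1, both n = 11: independent CDF evaluation
  expect_equal(variance_f_test(2, 11, 1, 11),
               2 * pf(4, 10, 10, lower.tail = FALSE), tolerance = 1e-12)
  # symmetric in group order
  expect_equal(variance_f_test(1, 11, 2, 11), variance_f_test(2, 11, 1, 11))
  # increasing the SD ratio decreases p
  ps <- sapply(c(1.2, 1.5, 2, 3), function(r) variance_f_test(r, 20, 1, 20))
  expect_true(all(diff(ps) < 0))
  # zero variance forces the Welch branch
  expect_equal(variance_f_test(0, 10, 1, 10), 0)
})

test_that("cohens_d_pooled reproduces printed effect sizes", {
  expect_equal(cohens_d_pooled(5, 1, 10, 5, 2, 14), 0)
  expect_lt(abs(cohens_d_pooled(0.18, 0.07, 102, 0.21, 0.10, 832) + 0.31),
            0.005)
  expect_lt(abs(cohens_d_pooled(28.75, 1.23, 102, 26.85, 2.29, 832) - 0.86),
            0.005)
})

test_that("t and d satisfy t = d * sqrt(n1 n2 / (n1 + n2)) identically", {
  set.seed(421)
  for (i in 1:50) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.2, 3); s2 <- runif(1, 0.2, 3)
    n1 <- sample(3:200, 1); n2 <- sample(3:200, 1)
    tt <- pooled_t(m1, s1, n1, m2, s2, n2)$t
    d <- cohens_d_pooled(m1, s1, n1, m2, s2, n2)
    expect_equal(tt, d * sqrt(n1 * n2 / (n1 + n2)), tolerance = 1e-10)
  }
})

test_that("statistics negate (t, d) or are invariant (F, chi2) on group swap", {
  set.seed(7)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.2, 3); s2 <- runif(1, 0.2, 3)
    n1 <- sample(3:100, 1); n2 <- sample(3:100, 1)
    expect_equal(pooled_t(m1, s1, n1, m2, s2, n2)$t,
                 -pooled_t(m2, s2, n2, m1, s1, n1)$t, tolerance = 1e-12)
    expect_equal(welch_t(m1, s1, n1, m2, s2, n2)$t,
                 -welch_t(m2, s2, n2, m1, s1, n1)$t, tolerance = 1e-12)
    expect_equal(cohens_d_pooled(m1, s1, n1, m2, s2, n2),
                 -cohens_d_pooled(m2, s2, n2, m1, s1, n1), tolerance = 1e-12)
    expect_equal(variance_f_test(s1, n1, s2, n2),
                 variance_f_test(s2, n2, s1, n1), tolerance = 1e-12)
  }
  tab <- matrix(c(10, 20, 20, 10), 2)
  expect_equal(chi_square_test(tab)$chisq, chi_square_test(t(tab))$chisq)
})

test_that("chi-square matches an expected-count loop oracle", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  # brute-force expected counts
  oracle <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / sum(tab)
    oracle <- oracle + (tab[i, j] - e)^2 / e
  }
  ct <- chi_square_test(tab)
  expect_equal(ct$chisq, oracle, tolerance = 1e-12)
  expect_equal(ct$chisq, 20 / 3, tolerance = 1e-12)
  expect_equal(ct$df, 1)
  # cross-check against the uncorrected standard implementation
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(ct$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-12)
  # perfectly proportional table
  expect_equal(chi_square_test(matrix(c(10, 20, 30, 60), 2))$chisq, 0)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("benjamini_hochberg implements the step-up rule", {
  expect_equal(benjamini_hochberg(rep(1, 6)), rep(FALSE, 6))
  # boundary: p_(5) = 0.05 = 5 * 0.05 / 5, so all five flagged
  expect_equal(benjamini_hochberg(c(0.001, 0.01, 0.02, 0.04, 0.05)),
               rep(TRUE, 5))
  # m = 1 reduces to the raw threshold
  expect_true(benjamini_hochberg(0.049))
  expect_false(benjamini_hochberg(0.051))
  expect_equal(benjamini_hochberg(numeric(0)), logical(0))
})

test_that("BH properties: permutation, Bonferroni superset, raw subset", {
  set.seed(422)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    fl <- benjamini_hochberg(p, q = 0.05)
    # equivalence with direct evaluation of the definition
    m <- length(p); ps <- sort(p)
    k <- which(ps <= seq_len(m) * 0.05 / m)
    direct <- if (length(k)) p <= ps[max(k)] else rep(FALSE, m)
    expect_equal(fl, direct)
    # equivalence with the standard step-up adjustment
    expect_equal(fl, unname(p.adjust(p, "BH") <= 0.05))
    # permutation invariance
    o <- sample(m)
    expect_equal(benjamini_hochberg(p[o], 0.05), fl[o])
    # Bonferroni flags subset of BH flags subset of raw flags
    expect_true(all(fl[p <= 0.05 / m]))
    expect_true(all(p[fl] <= 0.05))
  }
  # ties share fate
  p <- c(0.01, 0.03, 0.03, 0.8)
  fl <- benjamini_hochberg(p, 0.05)
  expect_equal(fl[2], fl[3])
})

test_that("pearson_r matches the sum-formula oracle and cor.test", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2.3, 1.9, 4.4, 6.1, 9.0)
  # explicit sum formula
  n <- 5
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  pr <- pearson_r(x, y)
  expect_equal(pr$r, r_hand, tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(pr$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(pr$p, ref$p.value, tolerance = 1e-12)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 3)$r, -1)
  expect_error(pearson_r(x, rep(1, 5)), "zero-variance")
})

test_that("compare_groups composes the per-operation oracles", {
  # identical groups: p = 1 everywhere, nothing flagged
  d <- data.frame(g = rep(c("a", "b"), each = 4),
                  x = rep(c(1, 2, 3, 4), 2),
                  s = rep(c("M", "F"), 4))
  cg <- compare_groups(d, "g", "x", categorical = "s")
  expect_equal(cg$statistic, c(0, 0))
  expect_equal(cg$p, c(1, 1))
  expect_false(any(cg$significant))

  # two-variable toy checked against the unit operations
  set.seed(7)
  d2 <- data.frame(g = rep(c("a", "b"), c(20, 25)),
                   u = c(rnorm(20, 0, 1), rnorm(25, 1, 3)),
                   v = rnorm(45))
  cg2 <- compare_groups(d2, "g", c("u", "v"), levels = c("a", "b"))
  for (v in c("u", "v")) {
    x1 <- d2[[v]][d2$g == "a"]; x2 <- d2[[v]][d2$g == "b"]
    fp <- variance_f_test(sd(x1), 20, sd(x2), 25)
    want <- if (fp < 0.05) {
      welch_t(mean(x1), sd(x1), 20, mean(x2), sd(x2), 25)
    } else pooled_t(mean(x1), sd(x1), 20, mean(x2), sd(x2), 25)
    row <- cg2[cg2$variable == v, ]
    expect_equal(row$statistic, want$t, tolerance = 1e-12)
    expect_equal(row$df, want$df, tolerance = 1e-9)
    expect_equal(row$test, if (fp < 0.05) "welch-t" else "pooled-t")
    expect_equal(row$cohens_d,
                 cohens_d_pooled(mean(x1), sd(x1), 20, mean(x2), sd(x2), 25),
                 tolerance = 1e-12)
  }
  # missing variables are skipped with a log entry
  expect_message(cg3 <- compare_groups(d2, "g", c("u", "nope")), "skipped")
  expect_equal(cg3$variable, "u")
})
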