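test_that("pooled-SD Cohen's d matches hand and published examples", {
  # published right-hemisphere OEF row: (46.99, 6.90, 15) vs (54.20, 7.35, 16)
  es <- cohens_d_from_summary(46.99, 6.90, 15, 54.20, 7.35, 16)
  expect_equal(es$d, 1.010, tolerance = 5e-4)
  expect_identical(es$interpretation, "large")

  expect_equal(cohens_d_from_summary(5, 1, 10, 5, 1, 10)$d, 0)
  expect_equal(cohens_d_from_summary(0, 1, 10, 1, 1, 10)$d, 1.0)

  # both SDs zero: undefined, flagged
  expect_true(is.na(cohens_d_from_summary(1, 0, 5, 2, 0, 5)$d))
})

test_that("summary-based d equals raw-sample d on moment-matched samples", {
  set.seed(10)
  for (i in 1:5) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    # affine-rescale draws so the sample moments are exactly the summary
    a <- rnorm(n1); a <- (a - mean(a)) / sd(a) * s1 + m1
    b <- rnorm(n2); b <- (b - mean(b)) / sd(b) * s2 + m2
    expect_equal(cohens_d(a, b),
                 cohens_d_from_summary(m1, s1, n1, m2, s2, n2)$d,
                 tolerance = 1e-12)
  }
})

test_that("interpretation boundaries are exactly as published", {
  expect_identical(interpret_d(c(0, 0.19, 0.2, 0.49, 0.5, 0.79, 0.8, 2)),
                   c("trivial", "trivial", "small", "small",
                     "medium", "medium", "large", "large"))
  expect_identical(interpret_r(c(0, 0.09, 0.1, 0.29, 0.3, 0.49, 0.5, 1)),
                   c("trivial", "trivial", "small", "small",
                     "medium", "medium", "large", "large"))
})

test_that("normality gate selects t for normal and Mann-Whitney for skewed", {
  set.seed(20)
  res_n <- choose_and_run_test(rnorm(30), rnorm(30, 1))
  expect_identical(res_n$test, "student_t")

  res_ln <- choose_and_run_test(rlnorm(200, 0, 1.5), rlnorm(200, 0.1, 1.5))
  expect_identical(res_ln$test, "mann_whitney")
  expect_true(res_ln$r >= 0 && res_ln$r <= 1)

  # identical samples: p in the ~1 region, d = 0
  x <- rnorm(20)
  res_same <- choose_and_run_test(x, x)
  expect_gt(res_same$p, 0.9)
  expect_equal(res_same$d, 0)

  # degenerate (all ties in both groups) flagged
  res_deg <- choose_and_run_test(rep(1, 5), rep(1, 6))
  expect_identical(res_deg$test, "degenerate")
  expect_true(is.na(res_deg$p))

  # Welch option
  res_w <- choose_and_run_test(rnorm(30), rnorm(30, 1), var_equal = FALSE)
  expect_identical(res_w$test, "welch_t")
})

test_that("categorical tests follow the expected-count rule", {
  # published sex split 12/3 vs 13/3: expected cells < 5 -> Fisher,
  # non-significant; forced chi-square reproduces the printed ~0.93
  tab <- matrix(c(12, 3, 13, 3), nrow = 2, byrow = TRUE)
  auto <- categorical_test(tab)
  expect_identical(auto$test, "fisher_exact")
  expect_gt(auto$p, 0.5)
  forced <- categorical_test(tab, method = "chisq")
  expect_equal(forced$p, 0.93, tolerance = 0.005)

  # identical rows: Fisher p = 1
  expect_equal(categorical_test(matrix(c(5, 5, 5, 5), 2))$p, 1)

  # (10,0 / 0,10): exhaustive hypergeometric oracle
  # two-sided p = 2 * P(X = 10 | margins) = 2 / choose(20, 10)
  extreme <- categorical_test(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_identical(extreme$test, "fisher_exact")
  p_oracle <- 0
  for (k in 0:10) {
    pk <- choose(10, k) * choose(10, 10 - k) / choose(20, 10)
    p0 <- choose(10, 10) * choose(10, 0) / choose(20, 10)
    if (pk <= p0 + 1e-12) p_oracle <- p_oracle + pk
  }
  expect_equal(extreme$p, p_oracle, tolerance = 1e-12)
  expect_equal(p_oracle, 2 / choose(20, 10), tolerance = 1e-15)

  expect_error(categorical_test(matrix(0L, 2, 2)), "empty")
})

test_that("correlation wrapper covers both methods and degeneracies", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(correlate(x, x)$r, 1)
  set.seed(30)
  y <- -x
  expect_equal(correlate(x, y)$r, -1)
  expect_identical(correlate(x, y)$r_interpretation, "large")
  sp <- correlate(x, x^3, method = "spearman")
  expect_equal(sp$r, 1)   # monotone map: rank correlation 1
  expect_true(is.na(correlate(x, rep(1, 6))$r))
})

test_that("sample correlation concentrates near the population value", {
  # bivariate normal with rho = -0.68 at n = 15 (the strongest reported
  # sleep-stage correlation magnitude); mean sample r within 0.05
  set.seed(40)
  rho <- -0.68; n <- 15
  rs <- replicate(1000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cor(x, y)
  })
  expect_lt(abs(mean(rs) - rho), 0.05)
})

test_that("Bonferroni adjustment is capped, monotone, order-preserving", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  set.seed(50)
  p <- runif(20)
  adj <- bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_identical(order(adj), order(pmin(1, length(p) * p)))
  expect_equal(adj, stats::p.adjust(p, "bonferroni"))
})

test_that("report_table reproduces published effect sizes from a cohort", {
  spec <- osa_oef_summary()
  spec <- spec[spec$es_is_pooled_d, ]
  co <- simulate_cohort(spec, seed = 2L)
  rep <- report_table(co, group_order = c("OSA", "HC"))
  expect_identical(nrow(rep), nrow(spec))
  expect_true(all(c("p", "p_bonferroni", "d", "d_interpretation",
                    "r", "r_interpretation") %in% names(rep)))
  expect_true(all(rep$p_bonferroni >= rep$p))
  expect_true(all(!is.na(rep$d_interpretation)))

  # effect sizes recomputed from the printed summaries themselves
  # reproduce the printed column within +/- 0.01
  d <- cohens_d_from_summary(spec$mean_a, spec$sd_a, spec$n_a,
                             spec$mean_b, spec$sd_b, spec$n_b)$d
  expect_true(all(abs(d - spec$es_printed) <= 0.01))
})
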