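test_that("the vulval induction index is total induced over animals", {
  expect_identical(vulval_index(rep(3, 12)), 3)
  expect_identical(vulval_index(c(3, 3, 4, 2)), 3)
  expect_identical(vulval_index(3.5), 3.5)
  expect_error(vulval_index(numeric(0)), class = "acquant_bad_param")
  expect_error(vulval_index(c(3, 7)), class = "acquant_bad_param")
})

test_that("VI is linear under cohort pooling", {
  a <- c(3, 3.5, 2); b <- c(4, 4, 3, 3, 3)
  pooled <- vulval_index(c(a, b))
  expect_equal(pooled, (length(a) * vulval_index(a) + length(b) * vulval_index(b)) /
                 (length(a) + length(b)))
})

test_that("per-animal induction phenotypes use strict comparisons against 3", {
  expect_identical(classify_induction(c(4, 3, 2.5, 3.5, 0)),
                   c("hyperinduced", "wild-type", "hypo-induced",
                     "hyperinduced", "hypo-induced"))
})

test_that("bootstrap of a constant vector is degenerate", {
  b <- bootstrap_mean(rep(2.5, 8), n_resamples = 1000, seed = 1)
  expect_identical(b$point_estimate, 2.5)
  expect_identical(b$sem, 0)
  expect_identical(diff(b$ci95), 0)
})

test_that("bootstrap sem of {0,1} matches the exhaustive enumeration", {
  # all 2^2 equally likely resamples have means {0, 0.5, 0.5, 1};
  # population SD of that distribution is sqrt(0.125)
  enumerated <- sqrt(mean((c(0, 0.5, 0.5, 1) - 0.5)^2))
  b <- bootstrap_mean(c(0, 1), n_resamples = 10000, seed = 7)
  expect_lt(abs(b$sem - enumerated), 0.01)
  expect_equal(b$point_estimate, 0.5)
})

test_that("bootstrap sem approaches the analytic s/sqrt(n) for normal draws", {
  set.seed(11)
  x <- rnorm(50, mean = 3, sd = 2)
  b <- bootstrap_mean(x, n_resamples = 10000, seed = 3)
  analytic <- sd(x) / sqrt(length(x))
  expect_lt(abs(b$sem - analytic) / analytic, 0.15)
})

test_that("bootstrap is deterministic given a seed and error shrinks with resamples", {
  x <- c(0, 1)
  expect_identical(bootstrap_mean(x, 2000, seed = 5)$sem,
                   bootstrap_mean(x, 2000, seed = 5)$sem)
  target <- sqrt(0.125)
  errs <- vapply(c(100L, 2000L, 40000L), function(B) {
    reps <- vapply(1:8, function(s) bootstrap_mean(x, B, seed = s)$sem, numeric(1))
    mean(abs(reps - target))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("normal-interval CI flavour is available and recorded", {
  x <- c(1, 2, 3, 4, 5)
  b <- bootstrap_mean(x, 2000, seed = 1, ci_method = "normal")
  expect_identical(b$ci_method, "normal")
  expect_equal(b$ci95, mean(x) + c(-1.96, 1.96) * b$sem)
})

test_that("fate-shift tabulation counts departures from P6.p", {
  expect_equal(fate_shift_table(rep("P6.p", 15))$percent_shifted, 0)
  t1 <- fate_shift_table(c(rep("P6.p", 19), "P5.p"))
  expect_equal(t1$percent_shifted, 5)
  expect_identical(unname(t1$counts["P5.p"]), 1L)
  expect_error(fate_shift_table(c("P6.p", "P4.p")), class = "acquant_bad_param")
  expect_error(fate_shift_table(character(0)), class = "acquant_bad_param")
})

test_that("t tests agree with the textbook Welch formula", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0); y <- c(27.1, 22.0, 20.8, 23.4)
  w <- welch_t(x, y)
  se <- sqrt(var(x) / 5 + var(y) / 4)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 5)^2 / 4 + (var(y) / 4)^2 / 3)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  s <- c(1, 2, 3)
  expect_equal(welch_t(s, s)$t, 0); expect_equal(welch_t(s, s)$p, 1)
  expect_equal(student_t(s, s)$p, 1)
  # clear separation
  expect_lt(student_t(s, s + 50)$p, 0.01)
  expect_error(welch_t(c(1, 1), c(1, 1)), class = "acquant_degenerate_input")
})

test_that("Mann-Whitney is exact by enumeration at small n", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_match(r$method, "exact")
  # identical multisets -> p = 1
  expect_equal(mann_whitney_u(c(5, 5, 7), c(5, 5, 7))$p, 1)
  # random small instances against the pairwise-count enumeration oracle
  set.seed(8)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:8, n1, replace = TRUE); y <- sample(1:8, n2, replace = TRUE)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p, oracle_mw_p(x, y), tolerance = 1e-12)
    # and against stats::wilcox.test when tie-free
    xf <- x + runif(n1) / 100; yf <- y + runif(n2) / 100
    expect_equal(mann_whitney_u(xf, yf)$p,
                 wilcox.test(xf, yf, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("the large-sample Mann-Whitney approximation tracks enumeration", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, 0, 2))
    exact <- mann_whitney_u(x, y)$p
    approx <- mann_whitney_u(x, y, exact_max_n = 0L)$p
    expect_lt(abs(exact - approx), 0.05)
  }
})

test_that("the variance F test doubles the upper tail of the larger ratio", {
  s <- c(3, 1, 4, 1, 5)
  expect_equal(f_test_variance(s, s)$F, 1)
  expect_equal(f_test_variance(s, s)$p, 1)
  set.seed(4)
  x <- rnorm(20, sd = 10); y <- rnorm(20, sd = 1)
  r <- f_test_variance(x, y)
  expect_lt(r$p, 0.001)
  # independent cross-check against stats::var.test (two-sided); skip
  # variance ratios so close to 1 that the two-sided constructions pick
  # different tails
  for (i in 1:20) {
    a <- rnorm(sample(5:15, 1)); b <- rnorm(sample(5:15, 1), sd = runif(1, 0.5, 2))
    res <- f_test_variance(a, b)
    if (res$F < 1.3) next
    expect_equal(res$p, var.test(a, b)$p.value, tolerance = 1e-9)
  }
  expect_error(f_test_variance(c(1, 1), c(1, 2)), class = "acquant_degenerate_input")
})

test_that("Fisher's exact test matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1)
  extreme <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact(extreme)$p, oracle_fisher_p(extreme), tolerance = 1e-12)
  expect_lt(fisher_exact(extreme)$p, 1e-4)
  set.seed(13)
  for (i in 1:60) {
    tbl <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) next
    expect_equal(fisher_exact(tbl)$p, oracle_fisher_p(tbl), tolerance = 1e-12)
    expect_equal(fisher_exact(tbl)$p, fisher.test(tbl)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "acquant_degenerate_input")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), class = "acquant_bad_param")
})
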