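# Induction statistics and the hypothesis-test battery. All tests are
# two-sided; no multiple-testing correction is applied (per-comparison
# reporting), which is documented rather than silently assumed.

induced_counts <- function(cohort) {
  x <- if (is.numeric(cohort)) cohort
       else if (is.data.frame(cohort)) cohort$induced_count
       else if (is.list(cohort)) vapply(cohort, function(a) a$induced_count, numeric(1))
       else NULL
  if (is.null(x) || length(x) < 1L)
    abort_acq("empty induction cohort", "acquant_bad_param")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 6))
    abort_acq("induced counts must be in [0, 6]", "acquant_bad_param")
  x
}

#' Vulval induction index (VI)
#'
#' Total number of induced VPCs divided by the number of animals scored.
#' Wild-type animals have exactly three induced cells (P5.p-P7.p), so a
#' pure wild-type cohort has VI = 3; VI > 3 indicates hyperinduction
#' (Muv-like), VI < 3 hypoinduction (Vul-like). Counts may be in steps of
#' 0.5 (half-induced VPCs).
#'
#' @param cohort Numeric vector of induced counts, a data frame with an
#'   `induced_count` column, or a list of [annotated_animal()]s.
#' @return The VI (numeric scalar).
#' @examples
#' vulval_index(c(3, 3, 4, 2))
#' @export
vulval_index <- function(cohort) {
  x <- induced_counts(cohort)
  sum(x) / length(x)
}

#' Classify a per-animal induction phenotype
#'
#' Strict comparisons against the wild-type count of 3: > 3 hyperinduced,
#' < 3 hypo-induced, exactly 3 wild-type.
#'
#' @param induced_count Induced count(s) for single animals.
#' @return Character vector of `"hyperinduced"`, `"wild-type"`,
#'   `"hypo-induced"`.
#' @export
classify_induction <- function(induced_count) {
  x <- induced_counts(induced_count)
  ifelse(x > 3, "hyperinduced", ifelse(x < 3, "hypo-induced", "wild-type"))
}

#' Bootstrap mean with s.e.m. and 95% CI
#'
#' Draws `n_resamples` resamples of size `n` with replacement, reports
#' the sample mean, the standard deviation of the resample means as the
#' s.e.m., and by default the 2.5/97.5 percentiles of the resample means
#' as the 95% CI (`ci_method = "normal"` gives mean +/- 1.96 s.e.m.
#' instead). Deterministic given `seed`.
#'
#' @param values Numeric vector (>= 1 value).
#' @param n_resamples Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @return Object of class `bootstrap_result`: `point_estimate`, `sem`,
#'   `ci95`, `n_resamples`, `seed`, `ci_method`.
#' @examples
#' bootstrap_mean(c(0, 1, 1, 3), n_resamples = 1000, seed = 2)
#' @export
bootstrap_mean <- function(values, n_resamples = 10000L, seed = 1L,
                           ci_method = c("percentile", "normal")) {
  ci_method <- match.arg(ci_method)
  if (length(values) < 1L || any(!is.finite(values)))
    abort_acq("`values` must be a non-empty finite numeric vector", "acquant_bad_param")
  n <- length(values)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n_resamples)
    rowMeans(matrix(values[idx], nrow = n_resamples))
  })
  sem <- stats::sd(means)
  if (n == 1L) sem <- 0   # sd() of identical resample means, guard NA at n=1
  ci <- if (ci_method == "percentile")
          unname(stats::quantile(means, c(0.025, 0.975)))
        else mean(values) + c(-1.96, 1.96) * sem
  structure(list(point_estimate = mean(values), sem = sem, ci95 = ci,
                 n_resamples = as.integer(n_resamples), seed = as.integer(seed),
                 ci_method = ci_method),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> mean %.4g, s.e.m. %.4g, 95%% CI [%.4g, %.4g] (%s, %d resamples, seed %d)\n",
              x$point_estimate, x$sem, x$ci95[1], x$ci95[2], x$ci_method,
              x$n_resamples, x$seed))
  invisible(x)
}

#' Primary-fate shift tabulation
#'
#' Counts at which VPC each animal's primary vulval fate was scored and
#' the percentage of animals whose primary fate shifted away from P6.p
#' (to P5.p or P7.p).
#'
#' @param cohort Data frame with a `primary_fate_vpc` column, or list of
#'   [annotated_animal()]s.
#' @return List: `counts` (named P5.p/P6.p/P7.p), `n`,
#'   `percent_shifted`.
#' @export
fate_shift_table <- function(cohort) {
  pf <- if (is.data.frame(cohort)) cohort$primary_fate_vpc
        else if (is.list(cohort) && !is.null(cohort[[1]]$primary_fate_vpc))
          vapply(cohort, function(a) a$primary_fate_vpc, character(1))
        else as.character(cohort)
  pf <- pf[!is.na(pf)]
  if (length(pf) < 1L) abort_acq("no primary-fate records", "acquant_bad_param")
  ok <- c("P5.p", "P6.p", "P7.p")
  if (!all(pf %in% ok))
    abort_acq(paste0("primary fate labels must be among ", paste(ok, collapse = "/"),
                     "; got: ", paste(setdiff(unique(pf), ok), collapse = ", ")),
              "acquant_bad_param")
  counts <- table(factor(pf, levels = ok))
  list(counts = counts, n = length(pf),
       percent_shifted = 100 * sum(pf != "P6.p") / length(pf))
}

check_two_samples <- function(x, y, min_n = 2L) {
  if (length(x) < min_n || length(y) < min_n ||
      any(!is.finite(x)) || any(!is.finite(y)))
    abort_acq(sprintf("each sample needs >= %d finite values", min_n),
              "acquant_bad_param")
}

#' Two-sample t tests
#'
#' `welch_t()` is the unequal-variance (Welch-Satterthwaite) form used
#' for comparing polarity-index distributions; `student_t()` the
#' equal-variance form. Both are two-sided.
#'
#' @param x,y Numeric samples (>= 2 values each).
#' @return List: `t`, `p`, `df`, `method`.
#' @export
welch_t <- function(x, y) t_two_sample(x, y, var_equal = FALSE)

#' @rdname welch_t
#' @export
student_t <- function(x, y) t_two_sample(x, y, var_equal = TRUE)

t_two_sample <- function(x, y, var_equal) {
  check_two_samples(x, y)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    abort_acq("degenerate input: both samples have zero variance",
              "acquant_degenerate_input")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       method = if (var_equal) "student" else "welch")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample sizes up to
#' `exact_max_n` (default 12) the p-value is exact, from full enumeration
#' of all group assignments of the pooled mid-ranks (a permutation test,
#' so ties are handled exactly); larger samples use the normal
#' approximation with tie correction and continuity correction. The
#' method used is recorded in the result.
#'
#' @param x,y Numeric samples (>= 1 value each).
#' @param exact_max_n Switch point on n_x + n_y for the exact path.
#' @return List: `U` (for `x`), `p`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 12L) {
  check_two_samples(x, y, min_n = 1L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))   # mid-ranks for ties
  u_stat <- function(r1) sum(r1) - n1 * (n1 + 1) / 2
  u_obs <- u_stat(rk[seq_len(n1)])
  mu <- n1 * n2 / 2
  if (N <= exact_max_n) {
    combs <- utils::combn(N, n1)
    us <- apply(combs, 2, function(ix) u_stat(rk[ix]))
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sigma == 0) return(list(U = u_obs, p = 1, method = "normal approximation"))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie + continuity corrected)"
  }
  list(U = u_obs, p = p, method = method)
}

#' Two-sided F test for equality of variances
#'
#' F is the larger sample variance over the smaller, with degrees of
#' freedom matched to the ordering; the two-sided p doubles the upper
#' tail (capped at 1). Used to report differences in the spread of
#' measured indices between genotypes.
#'
#' @param x,y Numeric samples (>= 2 values, positive variances).
#' @return List: `F`, `p`, `df`.
#' @export
f_test_variance <- function(x, y) {
  check_two_samples(x, y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 || v2 == 0)
    abort_acq("zero variance: F test undefined", "acquant_degenerate_input")
  if (v1 >= v2) { f <- v1 / v2; df <- c(length(x) - 1L, length(y) - 1L) }
  else          { f <- v2 / v1; df <- c(length(y) - 1L, length(x) - 1L) }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(F = f, p = p, df = df)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p summing, over all tables with the observed margins, the
#' hypergeometric probabilities not exceeding that of the observed table
#' (with the customary relative tolerance on the comparison).
#'
#' @param tbl 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List: `p`, `odds_ratio` (sample OR, `Inf`/0 at zero cells),
#'   `table`.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))$p
#' @export
fisher_exact <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == 2L) || any(tbl < 0) || any(tbl != round(tbl)))
    abort_acq("`tbl` must be a 2x2 matrix of non-negative integers", "acquant_bad_param")
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
    abort_acq("zero margin: Fisher's exact test undefined", "acquant_degenerate_input")
  m <- sum(tbl[1, ]); n <- sum(tbl[2, ]); k <- sum(tbl[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tbl[1, 1], m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- (tbl[1, 1] * tbl[2, 2]) / (tbl[1, 2] * tbl[2, 1])
  list(p = min(1, p), odds_ratio = or, table = tbl)
}
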