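# Shared fixtures: small noiseless parameter sets and brute-force oracles.

# Noiseless, puncta-free AC stack parameters (background optional).
quiet_params <- function(rho_dv = 1, rho_ap = 1, background = 0, ...) {
  ac_stack_params(rho_dv = rho_dv, rho_ap = rho_ap, n_punctae = 0L,
                  background = background, gaussian_noise_sd = 0,
                  poisson_noise = FALSE, ...)
}

# Brute-force two-loop polarity index oracle: explicit per-pixel loop,
# no vectorized shortcuts shared with the implementation.
oracle_polarity_dv <- function(pixels, mask, cy) {
  sv <- sd_ <- 0; nv <- nd <- 0L
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      if (!mask[i, j]) next
      y <- i - 1
      if (y > cy) { sv <- sv + pixels[i, j]; nv <- nv + 1L }
      else if (y < cy) { sd_ <- sd_ + pixels[i, j]; nd <- nd + 1L }
    }
  }
  (sv / nv) / (sd_ / nd)
}

# Enumeration oracle for the two-sided Fisher p: walk every table with
# the observed margins and sum the probabilities of tables no more
# probable than the observed one.
oracle_fisher_p <- function(tbl) {
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ]); c1 <- sum(tbl[, 1]); n <- r1 + r2
  p_obs <- choose(r1, tbl[1, 1]) * choose(r2, c1 - tbl[1, 1]) / choose(n, c1)
  tot <- 0
  for (a in 0:min(r1, c1)) {
    if (c1 - a > r2) next
    p <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
    if (p <= p_obs * (1 + 1e-7)) tot <- tot + p
  }
  min(1, tot)
}

# Enumeration oracle for the two-sided Mann-Whitney p at small n: counts
# pairwise wins directly (not via ranks) for every assignment of the
# pooled values into the two groups.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x); n2 <- length(y)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  mu <- n1 * n2 / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
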