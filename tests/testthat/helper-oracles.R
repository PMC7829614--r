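# Shared fixtures and independent oracles used across test files.

# Small, fast generator configuration for clinical-only checks.
small_config <- function(...) {
  args <- list(n_patients = 120, n_genes = 300, module_size = 20,
               rna_qc_fail_rate = 0, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Exhaustive two-sided Fisher p-value by hypergeometric enumeration
# (point-probability method: sum the probabilities of all tables no more
# likely than the observed one).
fisher_enum_p <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  supp <- max(0, k - n2):min(n1, k)
  pr <- stats::dhyper(supp, n1, n2, k)
  obs <- stats::dhyper(x1, n1, n2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Exhaustive permutation null of the uncorrected chi-squared statistic on
# a 2x2 table: permuting arm labels fixes both margins, so the full
# permutation distribution is hypergeometric over the support. Mid-point
# convention at the observed atom (the standard continuity match against
# a continuous asymptotic reference).
chisq_perm_p <- function(x1, n1, x2, n2) {
  obs <- binary_test(x1, n1, x2, n2, method = "chisq")$statistic
  k <- x1 + x2
  supp <- max(0, k - n2):min(n1, k)
  pr <- stats::dhyper(supp, n1, n2, k)
  a <- supp; b <- n1 - a; cc <- k - a; d <- n2 - cc
  st <- (n1 + n2) * (a * d - b * cc)^2 /
    (as.numeric(a + b) * (cc + d) * (a + cc) * (b + d))
  st[!is.finite(st)] <- 0
  sum(pr[st > obs + 1e-9]) + 0.5 * sum(pr[abs(st - obs) <= 1e-9])
}

# Brute-force exact signed-rank two-sided p: enumerate all 2^n sign
# assignments of the absolute differences (tiny n only).
signed_rank_brute_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  lower <- mean(v_all <= v_obs + 1e-9)
  upper <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}
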