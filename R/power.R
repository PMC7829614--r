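#' Per-group sample size for two proportions
#'
#' Pooled normal-approximation formula
#' `n = (z_{1-a/2} sqrt(2 pbar qbar) + z_{power} sqrt(p1 q1 + p2 q2))^2 / delta^2`
#' rounded up, alongside the Fleiss continuity-corrected size and,
#' optionally, the smallest per-group n whose simulated power reaches the
#' target. The three are reported side by side rather than forced to
#' agree, because published protocol sizes rarely state which variant was
#' used.
#'
#' @param p_ref,p_alt assumed response probabilities (must differ).
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level.
#' @param simulate logical; also search for the simulation-based n.
#' @param reps simulation replicates per candidate n.
#' @param seed seed for the simulation search.
#' @return List with `formula_n`, `fleiss_n` and (when `simulate`)
#'   `simulated_n`.
#' @export
n_per_group <- function(p_ref = 0.20, p_alt = 0.55, power = 0.90,
                        alpha = 0.05, simulate = FALSE, reps = 5000,
                        seed = NULL) {
  if (p_ref == p_alt) stop("p_ref and p_alt must differ")
  if (power <= 0 || power >= 1) stop("power must lie strictly in (0, 1)")
  if (any(c(p_ref, p_alt) < 0 | c(p_ref, p_alt) > 1))
    stop("rates must be probabilities")
  delta <- abs(p_alt - p_ref)
  pbar <- (p_ref + p_alt) / 2
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n_raw <- (za * sqrt(2 * pbar * (1 - pbar)) +
              zb * sqrt(p_ref * (1 - p_ref) + p_alt * (1 - p_alt)))^2 / delta^2
  formula_n <- ceiling(n_raw)
  fleiss_n <- ceiling(n_raw / 4 * (1 + sqrt(1 + 4 / (n_raw * delta)))^2)
  out <- list(formula_n = formula_n, fleiss_n = fleiss_n)
  if (simulate) {
    if (!is.null(seed)) set.seed(seed)
    n <- max(2, formula_n - 10)
    while (power_sim(n, p_ref, p_alt, alpha, reps)$power < power) n <- n + 1
    out$simulated_n <- n
  }
  out
}

#' Simulated power of the uncorrected chi-squared test
#'
#' Draws `reps` two-arm trials with `n_per_group` patients per arm and
#' the given response probabilities, applies the two-sided Pearson
#' chi-squared test without continuity correction at level `alpha`, and
#' reports the rejection fraction with its binomial Monte-Carlo standard
#' error. Tables with a degenerate margin (all responders or none) never
#' reject.
#'
#' @param n_per_group patients per arm.
#' @param p_ref,p_alt response probabilities.
#' @param alpha two-sided level.
#' @param reps number of simulated trials (>= 1000 recommended).
#' @param seed optional seed.
#' @return List with `power`, `mc_se`, `reps`, `n_per_group`.
#' @export
power_sim <- function(n_per_group, p_ref, p_alt, alpha = 0.05,
                      reps = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_per_group
  x1 <- stats::rbinom(reps, n, p_ref)
  x2 <- stats::rbinom(reps, n, p_alt)
  a <- x1; b <- n - x1; c_ <- x2; d <- n - x2
  nn <- 2 * n
  stat <- nn * (a * d - b * c_)^2 /
    (as.numeric(a + b) * (c_ + d) * (a + c_) * (b + d))
  stat[!is.finite(stat)] <- 0
  crit <- stats::qchisq(1 - alpha, df = 1)
  pw <- mean(stat > crit)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / reps),
       reps = reps, n_per_group = n)
}

#' Recruitment target from the attrition chain
#'
#' Total patients to recruit so that, after the expected fractions of
#' ungradable biopsies and dropout, the required number of B-cell poor
#' patients remains: `n_poor / (prop_poor * (1 - ungradable) * (1 -
#' dropout))`, divided sequentially and rounded once, up, at the end.
#'
#' @param n_poor_required B-cell poor patients needed by the power
#'   calculation.
#' @param prop_poor expected B-cell poor fraction of recruits.
#' @param ungradable_rate expected fraction of ungradable biopsies.
#' @param dropout_rate expected dropout fraction.
#' @return Integer total recruitment target.
#' @export
recruitment_chain <- function(n_poor_required, prop_poor = 0.60,
                              ungradable_rate = 0.10, dropout_rate = 0.05) {
  if (prop_poor <= 0) stop("prop_poor must be positive")
  if (ungradable_rate >= 1 || dropout_rate >= 1)
    stop("attrition rates must be below 1")
  ceiling(n_poor_required /
            (prop_poor * (1 - ungradable_rate) * (1 - dropout_rate)))
}
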