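#' Risk difference between two proportions with Wald interval
#'
#' Difference in response proportions, alternative minus reference, in
#' percentage points, with the unpooled Wald (normal approximation)
#' confidence interval. A Newcombe score-based hybrid interval is offered
#' as an option. Display rounding is half-away-from-zero to whole
#' percentage points; unrounded values are always retained.
#'
#' @param x_ref,n_ref responders / group size in the reference arm.
#' @param x_alt,n_alt responders / group size in the alternative arm.
#' @param alpha two-sided significance level (0.05 gives a 95% CI).
#' @param ci_method `"wald"` (default) or `"newcombe"`.
#' @return One-row `data.frame` of class `comparison_result` with counts,
#'   `effect`, `ci_low`, `ci_high` (percentage points), rounded display
#'   columns and a `method` tag. The degenerate all-equal-proportion Wald
#'   case (zero-width interval) is flagged via the `degenerate` column.
#' @export
risk_difference <- function(x_ref, n_ref, x_alt, n_alt, alpha = 0.05,
                            ci_method = c("wald", "newcombe")) {
  ci_method <- match.arg(ci_method)
  .check_counts(x_ref, n_ref); .check_counts(x_alt, n_alt)
  p_ref <- x_ref / n_ref
  p_alt <- x_alt / n_alt
  effect <- 100 * (p_alt - p_ref)
  z <- stats::qnorm(1 - alpha / 2)
  if (ci_method == "wald") {
    se <- sqrt(p_ref * (1 - p_ref) / n_ref + p_alt * (1 - p_alt) / n_alt)
    lo <- effect - z * 100 * se
    hi <- effect + z * 100 * se
  } else {
    w_ref <- .wilson(x_ref, n_ref, z)
    w_alt <- .wilson(x_alt, n_alt, z)
    lo <- effect - 100 * sqrt((p_alt - w_alt[1])^2 + (w_ref[2] - p_ref)^2)
    hi <- effect + 100 * sqrt((w_alt[2] - p_alt)^2 + (p_ref - w_ref[1])^2)
  }
  out <- data.frame(
    n_ref = n_ref, x_ref = x_ref, n_alt = n_alt, x_alt = x_alt,
    effect = effect, ci_low = lo, ci_high = hi,
    effect_rounded = round_half_away(effect),
    ci_low_rounded = round_half_away(lo),
    ci_high_rounded = round_half_away(hi),
    method = ci_method,
    degenerate = (ci_method == "wald" && lo == hi),
    stringsAsFactors = FALSE
  )
  class(out) <- c("comparison_result", class(out))
  out
}

.wilson <- function(x, n, z) {
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

.check_counts <- function(x, n) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n))
    stop("counts must be scalar and non-missing")
  if (n < 1) stop("group size must be at least 1")
  if (x < 0 || x > n) stop("responder count must lie in [0, n]")
  invisible(TRUE)
}

#' Round half away from zero
#'
#' Display rounding used for whole-percent effects and interval bounds
#' (2.5 -> 3, -2.5 -> -3), unlike `round()`'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Two-proportion test: chi-squared or Fisher's exact
#'
#' Pearson chi-squared without continuity correction on the 2x2 table;
#' Fisher's exact two-sided test (point-probability method) when any
#' expected cell count is below 5. The method actually used is recorded.
#'
#' @inheritParams risk_difference
#' @param method `"auto"` (expected-cell rule), `"chisq"`, `"fisher"`, or
#'   `"chisq_yates"` for the continuity-corrected variant.
#' @return List with `p_value`, `method`, `statistic` (chi-squared
#'   statistic, `NA` for Fisher) and `expected` (2x2 expected counts).
#' @export
binary_test <- function(x_ref, n_ref, x_alt, n_alt,
                        method = c("auto", "chisq", "fisher", "chisq_yates")) {
  method <- match.arg(method)
  .check_counts(x_ref, n_ref); .check_counts(x_alt, n_alt)
  tab <- matrix(c(x_ref, n_ref - x_ref, x_alt, n_alt - x_alt),
                nrow = 2, byrow = TRUE,
                dimnames = list(arm = c("ref", "alt"),
                                response = c("yes", "no")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher" else "chisq"
  if (method == "fisher") {
    p <- stats::fisher.test(tab)$p.value
    stat <- NA_real_
  } else {
    ht <- suppressWarnings(
      stats::chisq.test(tab, correct = (method == "chisq_yates")))
    p <- ht$p.value
    stat <- unname(ht$statistic)
    if (is.na(p)) { p <- 1; stat <- 0 }  # degenerate margin
  }
  list(p_value = p, method = method, statistic = stat, expected = expected)
}

#' ANCOVA on change from baseline
#'
#' Fits `change ~ arm + baseline` by least squares and reports the
#' per-arm least-squares mean change (baseline covariate held at its
#' grand mean), the adjusted between-arm difference (reference minus
#' alternative, matching the published sign convention for continuous
#' endpoints), its confidence interval, and the p-value of the arm term.
#'
#' @param baseline,followup numeric vectors, aligned per patient.
#' @param arm two-level factor/character of treatment labels; the first
#'   level (after factoring) is the reference arm.
#' @param conf_level confidence level.
#' @return One-row `data.frame` of class `comparison_result` with
#'   `lsmean_ref`, `lsmean_alt`, their standard errors, `effect`,
#'   `ci_low`, `ci_high`, `p_value`, `method = "ancova"`.
#' @export
ancova_change <- function(baseline, followup, arm, conf_level = 0.95) {
  d <- .ancova_frame(baseline, followup, arm)
  fit <- stats::lm(change ~ arm + baseline, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("degenerate (collinear) ANCOVA design")
  lev <- levels(d$arm)
  nd <- data.frame(arm = factor(lev, levels = lev),
                   baseline = mean(d$baseline))
  pr <- stats::predict(fit, newdata = nd, se.fit = TRUE)
  est <- -stats::coef(fit)[[paste0("arm", lev[2])]]    # ref minus alt
  ci <- -rev(stats::confint(fit, paste0("arm", lev[2]), level = conf_level)[1, ])
  p <- summary(fit)$coefficients[paste0("arm", lev[2]), "Pr(>|t|)"]
  out <- data.frame(
    n_ref = sum(d$arm == lev[1]), n_alt = sum(d$arm == lev[2]),
    lsmean_ref = pr$fit[1], lsmean_alt = pr$fit[2],
    se_ref = pr$se.fit[1], se_alt = pr$se.fit[2],
    effect = est, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    p_value = p, method = "ancova", stringsAsFactors = FALSE
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Rank (Quade) ANCOVA on change from baseline
#'
#' Non-parametric analysis of covariance: ranks of the change are
#' regressed on ranks of the baseline, and the residuals are compared
#' across arms by one-way ANOVA. Invariant under monotone transforms of
#' the outcome. The reported effect is the reference-minus-alternative
#' difference in mean rank residuals (a direction, not a clinical-scale
#' estimate).
#'
#' @inheritParams ancova_change
#' @return One-row `comparison_result` with `method = "rank_ancova"`.
#' @export
rank_ancova_change <- function(baseline, followup, arm, conf_level = 0.95) {
  d <- .ancova_frame(baseline, followup, arm)
  ry <- rank(d$change)
  rx <- rank(d$baseline)
  res <- stats::resid(stats::lm(ry ~ rx))
  fit <- stats::lm(res ~ d$arm)
  lev <- levels(d$arm)
  p <- stats::anova(fit)[["Pr(>F)"]][1]
  est <- -stats::coef(fit)[[2]]
  ci <- -rev(stats::confint(fit, level = conf_level)[2, ])
  out <- data.frame(
    n_ref = sum(d$arm == lev[1]), n_alt = sum(d$arm == lev[2]),
    effect = est, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    p_value = p, method = "rank_ancova", stringsAsFactors = FALSE
  )
  class(out) <- c("comparison_result", class(out))
  out
}

.ancova_frame <- function(baseline, followup, arm) {
  stopifnot(length(baseline) == length(followup),
            length(baseline) == length(arm))
  keep <- stats::complete.cases(baseline, followup, arm)
  d <- data.frame(baseline = baseline[keep],
                  change = followup[keep] - baseline[keep],
                  arm = factor(as.character(arm[keep])))
  if (nlevels(d$arm) != 2) stop("arm must have exactly two levels")
  if (min(table(d$arm)) < 2) stop("need at least two patients per arm")
  d
}

#' Check ANCOVA residual-normality assumption
#'
#' Shapiro-Wilk test on the residuals of the `change ~ arm + baseline`
#' fit; the rank ANCOVA is the documented fallback when it fails.
#'
#' @inheritParams ancova_change
#' @param alpha rejection level for the assumption check (default 0.01).
#' @return Logical: `TRUE` when the normality assumption is not rejected.
#' @export
ancova_assumptions_ok <- function(baseline, followup, arm, alpha = 0.01) {
  d <- .ancova_frame(baseline, followup, arm)
  res <- stats::resid(stats::lm(change ~ arm + baseline, data = d))
  if (length(res) < 3) return(TRUE)
  if (length(res) > 5000) res <- res[seq_len(5000)]
  if (stats::sd(res) == 0) return(TRUE)
  stats::shapiro.test(res)$p.value >= alpha
}

#' Paired Wilcoxon signed-rank test of within-group change
#'
#' Two-sided signed-rank test of follow-up versus baseline. Zero
#' differences are dropped (documented convention). For n <= `exact_max`
#' retained pairs the p-value is exact, computed from the full null
#' distribution of the signed midrank sum by convolution — valid under
#' ties, where the classical exact formula is not. Larger samples use
#' the normal approximation with tie correction and continuity
#' correction.
#'
#' @param baseline,followup paired numeric vectors.
#' @param exact_max largest n for which the exact null is enumerated.
#' @return List with `p_value`, `statistic` (signed-rank V), `n_used`,
#'   `method` (`"wilcoxon_paired_exact"` or `"wilcoxon_paired_normal"`).
#' @export
within_group_change <- function(baseline, followup, exact_max = 50) {
  stopifnot(length(baseline) == length(followup))
  keep <- stats::complete.cases(baseline, followup)
  d <- followup[keep] - baseline[keep]
  if (length(d) == 0) stop("no complete pairs")
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = 0, n_used = 0,
                method = "wilcoxon_paired_exact"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  if (n <= exact_max) {
    w <- as.integer(round(2 * r))           # doubled midranks are integers
    p <- .signed_rank_exact_p(w, 2 * v)
    method <- "wilcoxon_paired_exact"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4   # midrank variance; exact under ties
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "wilcoxon_paired_normal"
  }
  list(p_value = p, statistic = v, n_used = n, method = method)
}

# Exact two-sided p for the signed-rank sum with integer weights w:
# null assigns each weight + or - with probability 1/2; statistic is the
# sum of the positive weights. Distribution built by convolution.
.signed_rank_exact_p <- function(w, v2) {
  total <- sum(w)
  dist <- numeric(total + 1)   # index k+1 = P(sum of included weights == k)
  dist[1] <- 1
  for (wi in w) {
    shifted <- c(rep(0, wi), dist[seq_len(total + 1 - wi)])
    dist <- (dist + shifted) / 2
  }
  lower <- sum(dist[seq_len(v2 + 1)])
  upper <- sum(dist[(v2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Treatment-by-pathotype interaction likelihood-ratio test
#'
#' Compares two nested logistic regressions of binary response: one with
#' pathotype and treatment main effects, the other adding their
#' interaction. The LRT statistic is twice the log-likelihood gain,
#' referred to chi-squared with the interaction degrees of freedom.
#'
#' @param response logical/0-1 response vector.
#' @param arm treatment labels (two levels present).
#' @param pathotype pathotype labels (two levels present).
#' @return List with `statistic`, `df`, `p_value`, and the two fitted
#'   deviances.
#' @export
interaction_lrt <- function(response, arm, pathotype) {
  keep <- stats::complete.cases(response, arm, pathotype)
  d <- data.frame(y = as.integer(response[keep]),
                  arm = factor(as.character(arm[keep])),
                  path = factor(as.character(pathotype[keep])))
  if (nlevels(d$arm) < 2 || nlevels(d$path) < 2)
    stop("both factors must have both levels present")
  reduced <- suppressWarnings(
    stats::glm(y ~ path + arm, family = stats::binomial(), data = d))
  full <- suppressWarnings(
    stats::glm(y ~ path * arm, family = stats::binomial(), data = d))
  if (!full$converged || any(abs(stats::coef(full)) > 12, na.rm = TRUE))
    stop("separation detected in the logistic fit; use an exact or penalized method")
  stat <- reduced$deviance - full$deviance
  df <- reduced$df.residual - full$df.residual
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       deviance_full = full$deviance, deviance_reduced = reduced$deviance)
}
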