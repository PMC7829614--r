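#' Multiple imputation by chained equations
#'
#' Fills missing values in the declared imputable columns by iterated
#' conditional draws: predictive mean matching (type-1, Bayesian
#' coefficient draws, k nearest donors) for numeric columns and Bayesian
#' logistic draws for binary columns. Every other column acts as a
#' predictor. Returns `m` completed datasets; estimates computed on them
#' are pooled with [pool_rubin()].
#'
#' @param data a `data.frame`.
#' @param imputable character vector of column names allowed to contain
#'   missing values; a column that is entirely missing is an error.
#' @param m number of completed datasets (default 20).
#' @param maxit chained-equation sweeps per dataset.
#' @param k number of predictive-mean-matching donors.
#' @param seed optional integer seed for reproducibility.
#' @return List of class `mi_result`: `completed` (list of `m`
#'   data.frames), `m`, `imputable`.
#' @export
impute_mi <- function(data, imputable, m = 20, maxit = 10, k = 5,
                      seed = NULL) {
  stopifnot(is.data.frame(data), all(imputable %in% names(data)))
  if (!is.null(seed)) set.seed(seed)
  other_na <- setdiff(names(data)[colSums(is.na(data)) > 0], imputable)
  if (length(other_na) > 0)
    stop("missing values outside the declared imputable columns: ",
         paste(other_na, collapse = ", "))
  for (v in imputable) {
    if (all(is.na(data[[v]])))
      stop("column entirely missing, cannot impute: ", v)
  }
  needs <- imputable[vapply(imputable, function(v) anyNA(data[[v]]), TRUE)]
  predictors <- setdiff(names(data),
                        names(data)[vapply(data, is.character, TRUE)])
  completed <- lapply(seq_len(m), function(im) {
    d <- data
    # initial fill: random draws from the observed margin
    for (v in needs) {
      mis <- is.na(d[[v]])
      d[[v]][mis] <- sample(d[[v]][!mis], sum(mis), replace = TRUE)
    }
    if (length(needs) == 0) return(d)
    for (it in seq_len(maxit)) {
      for (v in needs) {
        mis <- is.na(data[[v]])
        rhs <- setdiff(predictors, v)
        X <- stats::model.matrix(
          ~ ., data = d[, rhs, drop = FALSE])
        y <- d[[v]]
        d[[v]][mis] <- if (is.logical(y) || length(unique(y[!mis])) <= 2)
          .draw_logistic(y, X, mis) else .draw_pmm(y, X, mis, k)
      }
    }
    d
  })
  structure(list(completed = completed, m = m, imputable = imputable),
            class = "mi_result")
}

# type-1 PMM: beta-hat predictions for observed, Bayesian-draw
# predictions for missing, match each missing to k nearest observed.
.draw_pmm <- function(y, X, mis, k) {
  Xo <- X[!mis, , drop = FALSE]
  yo <- as.numeric(y[!mis])
  qr_fit <- stats::lm.fit(Xo, yo)
  keep <- !is.na(qr_fit$coefficients)
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[mis, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- max(1, length(yo) - length(beta))
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  xtx_inv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  beta_star <- beta + drop(chol(sigma2 * xtx_inv + diag(1e-12, ncol(Xo))) %*%
                             stats::rnorm(length(beta)))
  pred_obs <- drop(Xo %*% beta)
  pred_mis <- drop(Xm %*% beta_star)
  vapply(pred_mis, function(pm) {
    donors <- order(abs(pred_obs - pm))[seq_len(min(k, length(pred_obs)))]
    yo[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
}

.draw_logistic <- function(y, X, mis) {
  yo <- as.numeric(y[!mis])
  Xo <- X[!mis, , drop = FALSE]
  Xm <- X[mis, , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm.fit(Xo, yo, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  w <- fit$weights
  info <- crossprod(Xo * sqrt(pmax(w, 1e-8)))
  vcv <- tryCatch(chol2inv(chol(info + diag(1e-6, ncol(Xo)))),
                  error = function(e) diag(1e-6, ncol(Xo)))
  beta_star <- beta + drop(chol(vcv + diag(1e-12, ncol(Xo))) %*%
                             stats::rnorm(length(beta)))
  p <- stats::plogis(drop(Xm %*% beta_star))
  draws <- stats::rbinom(length(p), 1, p)
  if (is.logical(y)) as.logical(draws) else draws
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus `(1 + 1/m)`
#' times the between-imputation variance. The confidence interval and
#' p-value (test against zero) use the Barnard-Rubin small-sample
#' degrees of freedom; with zero between-imputation variance the normal
#' reference is used.
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @param conf_level confidence level.
#' @return List: `estimate`, `se`, `ci_low`, `ci_high`, `p_value`, `df`,
#'   `var_within`, `var_between`, `var_total`.
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  stopifnot(length(estimates) == length(variances), length(estimates) >= 1)
  m <- length(estimates)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  t_var <- ubar + (1 + 1 / m) * b
  if (b == 0 || m == 1) {
    df <- Inf
  } else {
    df <- (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2
  }
  se <- sqrt(t_var)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  p <- if (se == 0) ifelse(qbar == 0, 1, 0) else
    2 * stats::pt(-abs(qbar / se), df)
  list(estimate = qbar, se = se,
       ci_low = qbar - q * se, ci_high = qbar + q * se,
       p_value = p, df = df,
       var_within = ubar, var_between = b, var_total = t_var)
}

#' Apply an analysis to each completed dataset and pool
#'
#' Convenience wrapper: `fun` maps a completed `data.frame` to a list
#' with `estimate` and `se`; the results are pooled with [pool_rubin()].
#'
#' @param mi an `mi_result` from [impute_mi()].
#' @param fun function of a completed data.frame returning
#'   `list(estimate = , se = )`.
#' @param conf_level confidence level for the pooled interval.
#' @return The [pool_rubin()] list.
#' @export
mi_pool <- function(mi, fun, conf_level = 0.95) {
  stopifnot(inherits(mi, "mi_result"))
  res <- lapply(mi$completed, fun)
  pool_rubin(vapply(res, `[[`, numeric(1), "estimate"),
             vapply(res, `[[`, numeric(1), "se")^2,
             conf_level = conf_level)
}
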