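#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors for a genes-by-samples count matrix:
#' each sample's factor is the median, over genes whose counts are
#' positive in every sample, of the ratio of the sample's count to the
#' gene's geometric mean across samples. Factors are rescaled so their
#' geometric mean is 1, making a matrix with equal columns return factors
#' of exactly 1.
#'
#' @param counts non-negative integer matrix, genes as rows.
#' @return Positive numeric vector, one factor per sample (column).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  zero_samples <- colSums(counts) == 0
  if (any(zero_samples)) {
    nm <- colnames(counts)[zero_samples]
    if (is.null(nm)) nm <- which(zero_samples)
    stop("sample(s) with all-zero counts: ", paste(nm, collapse = ", "))
  }
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene has positive counts in every sample; cannot estimate size factors")
  ratios <- log(counts[use, , drop = FALSE]) - log_geo[use]
  sf <- exp(apply(ratios, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Variance-stabilising count transform
#'
#' Shifted-log transform of size-factor-normalised counts:
#' `log2(count / size_factor + 1)`. Monotone in counts, zero counts map
#' to zero, and jointly doubling a count and its size factor leaves the
#' value unchanged.
#'
#' @param counts non-negative matrix, genes as rows.
#' @param sf per-sample positive size factors; computed with
#'   [size_factors()] when omitted.
#' @return Numeric matrix of the same shape as `counts`.
#' @export
vst_transform <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  if (length(sf) != ncol(counts) || any(sf <= 0))
    stop("size factors must be positive, one per sample")
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Per-sample gene-module score
#'
#' Summarises transformed expression over a predefined gene set (e.g. a
#' B-cell lineage module) per sample. The per-sample aggregation is the
#' mean of the module genes' transformed values by default; the median is
#' offered as an option.
#'
#' @param transformed numeric matrix of transformed expression with gene
#'   ids as rownames and sample ids as colnames.
#' @param gene_set character vector of gene ids defining the module.
#' @param method aggregation across module genes: `"mean"` or `"median"`.
#' @param module_name label stored with the result.
#' @return `data.frame` with `sample_id` and `score`; attributes
#'   `n_module_genes_found`, `module_size`, `module_name`.
#' @export
module_score <- function(transformed, gene_set, method = c("mean", "median"),
                         module_name = "module") {
  method <- match.arg(method)
  if (is.null(rownames(transformed)))
    stop("transformed matrix must carry gene ids as rownames")
  found <- intersect(gene_set, rownames(transformed))
  if (length(found) == 0)
    stop("none of the module genes are present in the expression matrix")
  if (length(found) < 0.8 * length(gene_set))
    warning(sprintf("only %d of %d module genes found in the matrix",
                    length(found), length(gene_set)))
  sub <- transformed[found, , drop = FALSE]
  score <- if (method == "mean") colMeans(sub) else apply(sub, 2, stats::median)
  out <- data.frame(sample_id = colnames(transformed), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "n_module_genes_found") <- length(found)
  attr(out, "module_size") <- length(gene_set)
  attr(out, "module_name") <- module_name
  out
}

#' Median-cutoff molecular pathotype classification
#'
#' Classifies samples B-cell poor or B-cell rich by their module score
#' relative to the cohort median: scores at or below the median are
#' `bcell_poor`, above it `bcell_rich`. The cutoff is computed on the
#' classified cohort itself (no external reference), so the rule is
#' invariant under any strictly increasing transform of the scores.
#'
#' @param score numeric vector of module scores (>= 2 samples).
#' @return Factor of pathotype labels with attributes `cutoff` and
#'   `basis = "molecular"`.
#' @export
classify_molecular <- function(score) {
  score <- as.numeric(score)
  if (length(score) < 2) stop("need at least two samples to classify")
  if (length(unique(score)) == 1)
    stop("all module scores are identical; no median split possible")
  cutoff <- stats::median(score)
  lab <- ifelse(score <= cutoff, "bcell_poor", "bcell_rich")
  structure(factor(lab, levels = pathotype_levels()),
            cutoff = cutoff, basis = "molecular")
}

#' Cutoff sensitivity scan for the molecular classifier
#'
#' Re-runs the molecular poor/rich split at a grid of percentile cutoffs
#' around the median and recomputes the primary-endpoint risk difference
#' (tocilizumab minus rituximab) within the resulting B-cell poor
#' stratum at each cutoff, to check whether the median was an artefact.
#'
#' @param score module scores, one per sample.
#' @param response logical/0-1 primary-endpoint response per sample
#'   (`NA` = unevaluable, dropped row-wise).
#' @param treatment treatment labels per sample (`"rituximab"` /
#'   `"tocilizumab"`).
#' @param center,halfwidth,step percentile grid: cutoffs run from
#'   `center - halfwidth` to `center + halfwidth` in steps of `step`.
#' @param conf_level confidence level of the per-cutoff Wald interval.
#' @return `data.frame`, one row per percentile cutoff, with group sizes,
#'   responder counts, risk difference (percentage points), Wald CI,
#'   p-value and a `flagged` column marking cutoffs with an empty
#'   treatment cell.
#' @export
cutoff_scan <- function(score, response, treatment,
                        center = 50, halfwidth = 10, step = 1,
                        conf_level = 0.95) {
  stopifnot(length(score) == length(response),
            length(score) == length(treatment))
  treatment <- as.character(treatment)
  pct <- seq(center - halfwidth, center + halfwidth, by = step)
  rows <- lapply(pct, function(p) {
    cut <- stats::quantile(score, p / 100, names = FALSE)
    poor <- score <= cut
    ev <- poor & !is.na(response)
    x_ref <- sum(response[ev & treatment == "rituximab"])
    n_ref <- sum(ev & treatment == "rituximab")
    x_alt <- sum(response[ev & treatment == "tocilizumab"])
    n_alt <- sum(ev & treatment == "tocilizumab")
    base <- data.frame(percentile = p, cutoff = cut,
                       n_poor = sum(poor), n_rich = sum(!poor),
                       n_ref = n_ref, x_ref = x_ref,
                       n_alt = n_alt, x_alt = x_alt)
    if (n_ref == 0 || n_alt == 0) {
      cbind(base, effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
            p_value = NA_real_, flagged = TRUE)
    } else {
      rd <- risk_difference(x_ref, n_ref, x_alt, n_alt,
                            alpha = 1 - conf_level)
      pv <- binary_test(x_ref, n_ref, x_alt, n_alt)$p_value
      cbind(base, effect = rd$effect, ci_low = rd$ci_low,
            ci_high = rd$ci_high, p_value = pv, flagged = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$percentile), , drop = FALSE]
}
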