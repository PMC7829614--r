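#' Clinical Disease Activity Index (CDAI)
#'
#' Sum of the 28-joint tender and swollen counts and the patient and
#' evaluator global assessments of disease activity on 0--10 visual
#' analogue scales. Range 0--76; no acute-phase reactant enters.
#'
#' @param tjc28 tender joint count, integer in \[0, 28\].
#' @param sjc28 swollen joint count, integer in \[0, 28\].
#' @param patient_global patient global assessment, 0--10.
#' @param evaluator_global evaluator global assessment, 0--10.
#' @return Numeric vector of CDAI values. `NA` components give `NA`.
#' @examples
#' cdai(11, 6, 7.5, 6.3)  # 30.8
#' @export
cdai <- function(tjc28, sjc28, patient_global, evaluator_global) {
  .check_range(tjc28, 0, 28, "tjc28")
  .check_range(sjc28, 0, 28, "sjc28")
  .check_range(patient_global, 0, 10, "patient_global")
  .check_range(evaluator_global, 0, 10, "evaluator_global")
  tjc28 + sjc28 + patient_global + evaluator_global
}

#' 28-joint Disease Activity Score (DAS28)
#'
#' ESR variant: `0.56*sqrt(TJC) + 0.28*sqrt(SJC) + 0.70*log(ESR) + 0.014*GH`.
#' CRP variant: `0.56*sqrt(TJC) + 0.28*sqrt(SJC) + 0.36*log(CRP + 1) +
#' 0.014*GH + 0.96`. GH is the patient global health assessment on a
#' 0--100 mm visual analogue scale.
#'
#' @param tjc28,sjc28 28-joint tender/swollen counts.
#' @param marker ESR in mm/h (must be strictly positive) or CRP in mg/L
#'   (non-negative), according to `variant`.
#' @param global_vas100 patient global health, 0--100 mm.
#' @param variant `"esr"` or `"crp"`.
#' @return Numeric vector of DAS28 values.
#' @examples
#' das28(11, 6, 31, 65, variant = "esr")
#' @export
das28 <- function(tjc28, sjc28, marker, global_vas100, variant = c("esr", "crp")) {
  variant <- match.arg(variant)
  .check_range(tjc28, 0, 28, "tjc28")
  .check_range(sjc28, 0, 28, "sjc28")
  .check_range(global_vas100, 0, 100, "global_vas100")
  joints <- 0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28)
  if (variant == "esr") {
    if (any(!is.na(marker) & marker <= 0))
      stop("ESR must be strictly positive for the DAS28-ESR variant")
    joints + 0.70 * log(marker) + 0.014 * global_vas100
  } else {
    if (any(!is.na(marker) & marker < 0))
      stop("CRP must be non-negative")
    joints + 0.36 * log(marker + 1) + 0.014 * global_vas100 + 0.96
  }
}

#' EULAR response category from baseline and follow-up DAS28
#'
#' Good: improvement > 1.2 and attained DAS28 <= 3.2. Moderate:
#' improvement > 1.2 with attained > 3.2, or improvement in (0.6, 1.2\]
#' with attained <= 5.1. Otherwise none.
#'
#' @param das_baseline,das_followup DAS28 at baseline and follow-up.
#' @return Factor with levels `good`, `moderate`, `none` (`NA` propagates).
#' @export
eular_response <- function(das_baseline, das_followup) {
  impr <- das_baseline - das_followup
  out <- rep(NA_character_, length(impr))
  good <- impr > 1.2 & das_followup <= 3.2
  moderate <- (impr > 1.2 & das_followup > 3.2) |
    (impr > 0.6 & impr <= 1.2 & das_followup <= 5.1)
  ok <- !is.na(impr) & !is.na(das_followup)
  out[ok] <- "none"
  out[ok & moderate] <- "moderate"
  out[ok & good] <- "good"
  factor(out, levels = c("good", "moderate", "none"))
}

#' Binary and categorical endpoint flags at week 16
#'
#' Computes the trial's endpoint definitions from baseline and week-16
#' index values: CDAI50% (week-16 CDAI at or below half of baseline),
#' CDAI low disease activity (<= 10.1), CDAI major treatment response
#' (CDAI50% together with LDA), DAS28 LDA (<= 3.2) and remission (<= 2.6)
#' for both variants, and EULAR response categories. Comparisons use a
#' small tolerance so that one-decimal inputs on the boundary count as
#' met. `NA` week-16 values yield `NA` flags (unevaluable); population
#' rules downstream decide how those are handled.
#'
#' @param cdai_baseline,cdai_week16 CDAI at baseline and week 16.
#' @param das28_esr_baseline,das28_esr_week16 DAS28-ESR values.
#' @param das28_crp_baseline,das28_crp_week16 DAS28-CRP values.
#' @param tol comparison tolerance for the threshold rules.
#' @return A `data.frame` with logical columns `cdai50`, `cdai_lda`,
#'   `cdai_mtr`, `das28_esr_lda`, `das28_crp_lda`, `das28_esr_rem`,
#'   `das28_crp_rem` and factor columns `eular_esr`, `eular_crp`.
#' @export
endpoint_flags <- function(cdai_baseline, cdai_week16,
                           das28_esr_baseline, das28_esr_week16,
                           das28_crp_baseline, das28_crp_week16,
                           tol = 1e-9) {
  if (any(!is.na(cdai_baseline) & cdai_baseline == 0))
    warning("baseline CDAI of 0: CDAI50% evaluates TRUE by convention (0 <= 0)")
  cdai50 <- cdai_week16 <= 0.5 * cdai_baseline + tol
  cdai_lda <- cdai_week16 <= 10.1 + tol
  data.frame(
    cdai50 = cdai50,
    cdai_lda = cdai_lda,
    cdai_mtr = cdai50 & cdai_lda,
    das28_esr_lda = das28_esr_week16 <= 3.2 + tol,
    das28_crp_lda = das28_crp_week16 <= 3.2 + tol,
    das28_esr_rem = das28_esr_week16 <= 2.6 + tol,
    das28_crp_rem = das28_crp_week16 <= 2.6 + tol,
    eular_esr = eular_response(das28_esr_baseline, das28_esr_week16),
    eular_crp = eular_response(das28_crp_baseline, das28_crp_week16)
  )
}

.check_range <- function(x, lo, hi, name) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad))
    stop(sprintf("%s out of range [%g, %g]: %s", name, lo, hi,
                 paste(utils::head(x[bad], 3), collapse = ", ")))
  invisible(TRUE)
}
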