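#' Week-16 endpoint table by stratum
#'
#' Reproduces the published table structure for any stratification:
#' for each of the B-cell poor and B-cell rich strata it contrasts the
#' two arms on every binary endpoint (CDAI50%, CDAI-MTR, CDAI <= 10.1,
#' DAS28 low disease activity and remission in both variants, EULAR
#' moderate-or-good response in both variants) via [risk_difference()]
#' and [binary_test()], and on every continuous endpoint (CDAI, DAS28
#' both variants, HAQ, FACIT, SF36 physical and mental summaries,
#' change from baseline) via [ancova_change()] — falling back to
#' [rank_ancova_change()] when the residual-normality check fails.
#'
#' Binary endpoints are computed on evaluable patients (week-16 indices
#' observed) within the chosen population; `nonresponder_imputation =
#' TRUE` instead counts unevaluable patients as non-responders on the
#' full population denominator.
#'
#' @param dataset a `trial_dataset`.
#' @param stratification `"histology"` (biopsy pathotype) or
#'   `"molecular"` (median-cutoff module classification, which excludes
#'   GC-positive and QC-failed samples).
#' @param population `"itt"` (dosed patients) or `"per_protocol"` (ITT
#'   without major protocol violations).
#' @param nonresponder_imputation see above.
#' @param shapiro_alpha level of the ANCOVA assumption check.
#' @param conf_level confidence level.
#' @return `data.frame`, one row per endpoint x stratum, with counts or
#'   least-squares means, effect, CI, p-value and method tag. Rows with
#'   an empty stratum-arm cell are flagged.
#' @export
endpoint_table <- function(dataset,
                           stratification = c("histology", "molecular"),
                           population = c("itt", "per_protocol"),
                           nonresponder_imputation = FALSE,
                           shapiro_alpha = 0.01, conf_level = 0.95) {
  stratification <- match.arg(stratification)
  population <- match.arg(population)
  stopifnot(inherits(dataset, "trial_dataset"))
  p <- compute_indices(dataset$patients)
  labels <- if (stratification == "histology") p$histology_label else
    as.character(molecular_labels(dataset))
  pop <- p$dosed
  if (population == "per_protocol") pop <- pop & !p$protocol_violation
  binary_defs <- c(cdai50 = "cdai50", cdai_mtr = "cdai_mtr",
                   cdai_lda = "cdai_lda",
                   das28_esr_lda = "das28_esr_lda",
                   das28_crp_lda = "das28_crp_lda",
                   das28_esr_rem = "das28_esr_rem",
                   das28_crp_rem = "das28_crp_rem")
  cont_defs <- list(cdai_change = c("bl_cdai", "wk16_cdai"),
                    das28_esr_change = c("bl_das28_esr", "wk16_das28_esr"),
                    das28_crp_change = c("bl_das28_crp", "wk16_das28_crp"),
                    haq_change = c("bl_haq", "wk16_haq"),
                    facit_change = c("bl_facit", "wk16_facit"),
                    sf36_pcs_change = c("bl_sf36_pcs", "wk16_sf36_pcs"),
                    sf36_mcs_change = c("bl_sf36_mcs", "wk16_sf36_mcs"))
  out <- list()
  for (stratum in c("bcell_poor", "bcell_rich")) {
    in_stratum <- pop & !is.na(labels) & labels == stratum
    ref <- in_stratum & p$treatment == "rituximab"
    alt <- in_stratum & p$treatment == "tocilizumab"
    flags <- cbind(p[binary_defs],
                   eular_esr = p$eular_esr %in% c("good", "moderate") &
                     !is.na(p$eular_esr),
                   eular_crp = p$eular_crp %in% c("good", "moderate") &
                     !is.na(p$eular_crp))
    flags$eular_esr[is.na(p$eular_esr)] <- NA
    flags$eular_crp[is.na(p$eular_crp)] <- NA
    for (ep in colnames(flags)) {
      y <- flags[[ep]]
      if (nonresponder_imputation) {
        yr <- !is.na(y) & y
        n_ref <- sum(ref); x_ref <- sum(yr[ref])
        n_alt <- sum(alt); x_alt <- sum(yr[alt])
      } else {
        n_ref <- sum(ref & !is.na(y)); x_ref <- sum(y[ref], na.rm = TRUE)
        n_alt <- sum(alt & !is.na(y)); x_alt <- sum(y[alt], na.rm = TRUE)
      }
      if (n_ref == 0 || n_alt == 0) {
        out[[length(out) + 1]] <- data.frame(
          endpoint = ep, stratum = stratum, type = "binary",
          n_ref = n_ref, x_ref = x_ref, n_alt = n_alt, x_alt = x_alt,
          effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, method = NA_character_, flagged = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      rd <- risk_difference(x_ref, n_ref, x_alt, n_alt,
                            alpha = 1 - conf_level)
      bt <- binary_test(x_ref, n_ref, x_alt, n_alt)
      out[[length(out) + 1]] <- data.frame(
        endpoint = ep, stratum = stratum, type = "binary",
        n_ref = n_ref, x_ref = x_ref, n_alt = n_alt, x_alt = x_alt,
        effect = rd$effect, ci_low = rd$ci_low, ci_high = rd$ci_high,
        p_value = bt$p_value, method = bt$method, flagged = FALSE,
        stringsAsFactors = FALSE)
    }
    for (ep in names(cont_defs)) {
      v <- cont_defs[[ep]]
      idx <- in_stratum & stats::complete.cases(p[[v[1]]], p[[v[2]]])
      if (sum(idx & p$treatment == "rituximab") < 2 ||
          sum(idx & p$treatment == "tocilizumab") < 2) {
        out[[length(out) + 1]] <- data.frame(
          endpoint = ep, stratum = stratum, type = "continuous",
          n_ref = sum(idx & p$treatment == "rituximab"), x_ref = NA_integer_,
          n_alt = sum(idx & p$treatment == "tocilizumab"), x_alt = NA_integer_,
          effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, method = NA_character_, flagged = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      bl <- p[[v[1]]][idx]; fu <- p[[v[2]]][idx]
      arm <- factor(p$treatment[idx], levels = c("rituximab", "tocilizumab"))
      cr <- if (ancova_assumptions_ok(bl, fu, arm, alpha = shapiro_alpha))
        ancova_change(bl, fu, arm, conf_level) else
          rank_ancova_change(bl, fu, arm, conf_level)
      out[[length(out) + 1]] <- data.frame(
        endpoint = ep, stratum = stratum, type = "continuous",
        n_ref = cr$n_ref, x_ref = NA_integer_,
        n_alt = cr$n_alt, x_alt = NA_integer_,
        effect = cr$effect, ci_low = cr$ci_low, ci_high = cr$ci_high,
        p_value = cr$p_value, method = cr$method, flagged = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Safety summary table from adverse-event records
#'
#' Deduplicates recurrent identical events (same patient, same term),
#' then tabulates any adverse event, any serious adverse event, and
#' serious events by drug-relatedness, comparing arms as treated with
#' [risk_difference()].
#'
#' @param events `data.frame` with columns `patient_id`, `term`,
#'   `serious` (logical), `related` (logical).
#' @param arm_as_treated named character vector (or 2-column
#'   `data.frame` `patient_id`, `arm`) giving each safety-population
#'   patient's actual treatment.
#' @return `data.frame`, one row per safety endpoint, with per-arm
#'   affected-patient counts and the risk difference.
#' @export
safety_table <- function(events, arm_as_treated) {
  if (is.data.frame(arm_as_treated)) {
    arms <- stats::setNames(as.character(arm_as_treated$arm),
                            arm_as_treated$patient_id)
  } else arms <- arm_as_treated
  stopifnot(all(c("patient_id", "term", "serious") %in% names(events)))
  if (is.null(events$related)) events$related <- NA
  events <- unique(events[, c("patient_id", "term", "serious", "related")])
  if (!all(events$patient_id %in% names(arms)))
    stop("events reference patients absent from the as-treated arm map")
  pts <- names(arms)
  affected <- function(sub) pts %in% unique(sub$patient_id)
  defs <- list(
    any_ae = affected(events[!events$serious, , drop = FALSE]),
    any_sae = affected(events[events$serious, , drop = FALSE]),
    sae_related = affected(events[events$serious & events$related %in% TRUE, ,
                                  drop = FALSE]),
    sae_unrelated = affected(events[events$serious & events$related %in% FALSE, ,
                                    drop = FALSE]))
  ref <- arms == "rituximab"
  alt <- arms == "tocilizumab"
  rows <- lapply(names(defs), function(ep) {
    y <- defs[[ep]]
    rd <- risk_difference(sum(y[ref]), sum(ref), sum(y[alt]), sum(alt))
    cbind(endpoint = ep, rd)
  })
  do.call(rbind, rows)
}
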