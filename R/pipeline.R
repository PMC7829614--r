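#' Reference endpoint counts from the published trial tables
#'
#' Two-by-two endpoint counts for a biopsy-stratified rheumatoid
#' arthritis trial of rituximab (reference arm) versus tocilizumab
#' (alternative arm), as published in its 16-week outcome and safety
#' tables, together with the printed whole-percent treatment differences
#' and 95% confidence bounds. These counts are inputs for
#' [reproduce_printed_stats()]; they contain no patient-level data.
#'
#' @return `data.frame` with one row per endpoint x stratification.
#' @export
published_outcome_counts <- function() {
  path <- system.file("extdata", "published_counts.csv",
                      package = "pathotrial", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute published statistics from their printed counts
#'
#' For every published endpoint row whose four counts are printed,
#' recomputes the risk difference and Wald 95% interval, applies the
#' documented integer-percent rounding (half away from zero), records
#' the test the expected-cell rule selects, and compares against the
#' printed values. Printed tables are not perfectly consistent with any
#' single rounding rule, so both exact-match and within-one-point flags
#' are reported.
#'
#' @param counts optionally, a counts table shaped like
#'   [published_outcome_counts()] (used by the sensitivity tests).
#' @return The counts table with computed `effect`, `ci_low`, `ci_high`
#'   (unrounded), their rounded versions, the `test_method` tag, the
#'   recomputed p-value, and logical `match_exact` / `match_within_1`.
#' @export
reproduce_printed_stats <- function(counts = published_outcome_counts()) {
  res <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    rd <- risk_difference(r$x_ref, r$n_ref, r$x_alt, r$n_alt)
    bt <- binary_test(r$x_ref, r$n_ref, r$x_alt, r$n_alt)
    data.frame(effect = rd$effect, ci_low = rd$ci_low, ci_high = rd$ci_high,
               effect_rounded = rd$effect_rounded,
               ci_low_rounded = rd$ci_low_rounded,
               ci_high_rounded = rd$ci_high_rounded,
               p_value = bt$p_value, test_method = bt$method)
  })
  out <- cbind(counts, do.call(rbind, res))
  dev <- cbind(out$effect_rounded - out$printed_effect,
               out$ci_low_rounded - out$printed_lo,
               out$ci_high_rounded - out$printed_hi)
  out$match_exact <- rowSums(abs(dev)) == 0
  out$match_within_1 <- apply(abs(dev), 1, max) <= 1
  out
}

#' Run the full pipeline on one configuration
#'
#' Executes the declared stages in order — `simulate` (synthetic trial),
#' `classify` (histology and molecular labels), `indices` (composite
#' scores and endpoint flags), `analyze` (endpoint tables for the
#' requested stratifications), `power` (design calculations) — writing
#' every artifact under `out_dir` with an md5-checksummed manifest.
#' Re-running the same configuration reproduces identical checksums.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `out_dir` (required), `seed` (default 1), `stages` (default all),
#'   `sim` (list of [sim_config()] overrides), `stratification`
#'   (`"histology"`, `"molecular"` or both), `population`, and `power`
#'   (list of [n_per_group()] arguments).
#' @return The run manifest (invisibly), also written as
#'   `run_manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- if (is.null(config$stages))
    c("simulate", "classify", "indices", "analyze", "power") else config$stages
  strat <- if (is.null(config$stratification))
    c("histology", "molecular") else config$stratification
  population <- if (is.null(config$population)) "itt" else config$population
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character()
  dataset <- NULL
  labels_done <- FALSE

  if ("simulate" %in% stages) {
    sim_args <- if (is.null(config$sim)) list() else config$sim
    sim_args$seed <- seed
    dataset <- simulate_trial(do.call(sim_config, sim_args))
    write_dataset(dataset, file.path(out_dir, "dataset"), overwrite = TRUE)
    files <- c(files, file.path("dataset", "clinical.csv"),
               file.path("dataset", "histology.csv"))
  } else if (!is.null(config$dataset_dir)) {
    dataset <- read_dataset(config$dataset_dir)
  }

  if ("classify" %in% stages) {
    if (is.null(dataset))
      stop("stage 'classify' needs a dataset: run 'simulate' or give dataset_dir")
    p <- dataset$patients
    lab <- data.frame(patient_id = p$patient_id,
                      histology_label = p$histology_label,
                      stringsAsFactors = FALSE)
    if ("molecular" %in% strat && !is.null(dataset$expression)) {
      ml <- molecular_labels(dataset)
      lab$molecular_label <- as.character(ml)
      lab$module_score <- attr(ml, "score")
    }
    utils::write.csv(lab, file.path(out_dir, "labels.csv"), row.names = FALSE)
    files <- c(files, "labels.csv")
    labels_done <- TRUE
  }

  if ("indices" %in% stages) {
    if (is.null(dataset)) stop("stage 'indices' needs a dataset")
    idx <- compute_indices(dataset$patients)
    utils::write.csv(idx, file.path(out_dir, "indices.csv"), row.names = FALSE)
    files <- c(files, "indices.csv")
  }

  if ("analyze" %in% stages) {
    if (is.null(dataset)) stop("stage 'analyze' needs a dataset")
    if (!labels_done)
      stop("missing artifact: labels.csv (stage 'classify' must precede 'analyze')")
    for (s in strat) {
      if (s == "molecular" && is.null(dataset$expression)) next
      tab <- endpoint_table(dataset, stratification = s,
                            population = population)
      fn <- sprintf("endpoints_%s_%s.csv", s, population)
      utils::write.csv(tab, file.path(out_dir, fn), row.names = FALSE)
      files <- c(files, fn)
    }
  }

  if ("power" %in% stages) {
    pw_args <- if (is.null(config$power)) list() else config$power
    np <- do.call(n_per_group, pw_args)
    sim_pw <- power_sim(max(np$formula_n, 2),
                        if (is.null(pw_args$p_ref)) 0.20 else pw_args$p_ref,
                        if (is.null(pw_args$p_alt)) 0.55 else pw_args$p_alt,
                        reps = 5000, seed = seed)
    jsonlite::write_json(c(np, sim_pw), file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "power.json")
  }

  manifest <- list(seed = seed, stages = stages,
                   checksums = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
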