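#' Configuration for the synthetic trial generator
#'
#' Collects and validates every knob of the synthetic cohort. Defaults
#' encode the study conditions of a biopsy-stratified anti-TNF-refractory
#' rheumatoid arthritis trial: a latent B-cell rich/poor synovial state,
#' a 73-gene B-cell expression module elevated in rich patients,
#' ordinal CD20 immunohistochemistry correlated with the latent state,
#' poor-stratum response rates of 20% (rituximab) and 55% (tocilizumab),
#' near-identical rich-stratum rates, and modest missingness and dropout.
#' Rationales for the default values are laid out in the methods
#' vignette.
#'
#' @param n_patients number of randomized patients.
#' @param n_genes number of simulated genes.
#' @param module_size number of genes in the designated B-cell module
#'   (the first `module_size` gene ids).
#' @param prop_bcell_rich probability a patient is latently B-cell rich.
#' @param prop_gc_given_rich probability a (histologically) rich biopsy
#'   shows CD21+ follicular dendritic cell networks.
#' @param ungradable_rate probability no definite synovial tissue can be
#'   graded.
#' @param module_log_fold_change log2 elevation of module-gene expression
#'   in latently rich patients.
#' @param module_sample_sd per-sample log2 SD of module activity around
#'   its class mean (biological noise).
#' @param nb_dispersion shared negative-binomial dispersion of counts.
#' @param histology_concordance probability the ordinal CD20 score
#'   reflects the latent class.
#' @param response_rates list with elements `rituximab` and
#'   `tocilizumab`, each a named vector `c(poor = , rich = )` of week-16
#'   response probabilities.
#' @param missing_rate marginal probability of an item-level week-16 gap
#'   (applied to labs and patient-reported outcomes, MAR on baseline
#'   severity).
#' @param dropout_rate probability the week-16 visit is missing entirely.
#' @param not_dosed_rate probability a randomized patient never receives
#'   drug (excluded from ITT).
#' @param violation_rate probability of a major protocol violation
#'   (excluded from per-protocol).
#' @param rna_qc_fail_rate probability a biopsy fails RNA-seq QC/mapping
#'   (modelled as an input mask, not re-derived).
#' @param site_labels site-group labels (first label is the lead centre).
#' @param prop_first_site probability of recruitment at the lead centre.
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 160, n_genes = 20000, module_size = 73,
                       prop_bcell_rich = 0.45, prop_gc_given_rich = 0.12,
                       ungradable_rate = 0.06,
                       module_log_fold_change = 2, module_sample_sd = 0.3,
                       nb_dispersion = 0.3, histology_concordance = 0.9,
                       response_rates = list(
                         rituximab = c(poor = 0.20, rich = 0.50),
                         tocilizumab = c(poor = 0.55, rich = 0.48)),
                       missing_rate = 0.05, dropout_rate = 0.05,
                       not_dosed_rate = 0.02, violation_rate = 0.05,
                       rna_qc_fail_rate = 0.17,
                       site_labels = c("LEAD", "OTHER"),
                       prop_first_site = 0.38,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              module_size = as.integer(module_size),
              prop_bcell_rich = prop_bcell_rich,
              prop_gc_given_rich = prop_gc_given_rich,
              ungradable_rate = ungradable_rate,
              module_log_fold_change = module_log_fold_change,
              module_sample_sd = module_sample_sd,
              nb_dispersion = nb_dispersion,
              histology_concordance = histology_concordance,
              response_rates = response_rates,
              missing_rate = missing_rate, dropout_rate = dropout_rate,
              not_dosed_rate = not_dosed_rate,
              violation_rate = violation_rate,
              rna_qc_fail_rate = rna_qc_fail_rate,
              site_labels = as.character(site_labels),
              prop_first_site = prop_first_site,
              seed = as.integer(seed))
  probs <- c(cfg$prop_bcell_rich, cfg$prop_gc_given_rich, cfg$ungradable_rate,
             cfg$histology_concordance, cfg$missing_rate, cfg$dropout_rate,
             cfg$not_dosed_rate, cfg$violation_rate, cfg$rna_qc_fail_rate,
             cfg$prop_first_site, unlist(cfg$response_rates))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$module_size > cfg$n_genes) stop("module_size must not exceed n_genes")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (length(cfg$site_labels) == 0) stop("site_labels must be non-empty")
  for (arm in c("rituximab", "tocilizumab")) {
    r <- cfg$response_rates[[arm]]
    if (is.null(r) || !all(c("poor", "rich") %in% names(r)))
      stop("response_rates must have poor and rich entries for both arms")
  }
  if (cfg$n_patients < 1) stop("need at least one patient")
  structure(cfg, class = "sim_config")
}

#' Simulate a complete biopsy-stratified trial
#'
#' Generates, deterministically for a fixed seed, a full synthetic trial
#' with known ground truth: latent B-cell class, histology scores and
#' pathotype, stratified permuted-block treatment allocation, baseline
#' and week-16 clinical visits whose recomputed indices are consistent
#' with each patient's simulated responder status (responders improve
#' CDAI by at least 50%, non-responders strictly less), serology,
#' population flags, missing-at-random item gaps, dropout, and a
#' genes-by-patients negative-binomial expression matrix in which the
#' designated module is elevated in latently rich patients.
#'
#' @param config a [sim_config()] object.
#' @param expression logical; generate the expression matrix (set
#'   `FALSE` for clinical-only simulations).
#' @return A list of class `trial_dataset` with elements `patients`
#'   (one row per patient), `expression` (list: `counts`, `gene_ids`,
#'   `sample_ids`) or `NULL`, `gene_sets` (named list of gene-id
#'   vectors) and `config`.
#' @export
simulate_trial <- function(config = sim_config(), expression = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  latent <- ifelse(stats::runif(n) < config$prop_bcell_rich, "rich", "poor")

  # --- histology -----------------------------------------------------
  concordant <- stats::runif(n) < config$histology_concordance
  observed <- ifelse(concordant, latent,
                     ifelse(latent == "rich", "poor", "rich"))
  cd20 <- integer(n)
  cd20[observed == "poor"] <- sample(0:1, sum(observed == "poor"), replace = TRUE)
  cd20[observed == "rich"] <- sample(2:4, sum(observed == "rich"), replace = TRUE,
                                     prob = c(0.4, 0.35, 0.25))
  aggregates <- ifelse(observed == "rich",
                       stats::runif(n) < 0.9, stats::runif(n) < 0.1)
  gradable <- stats::runif(n) >= config$ungradable_rate
  cd21 <- observed == "rich" & gradable &
    stats::runif(n) < config$prop_gc_given_rich
  cd3 <- pmin(4L, cd20 + sample(-1:1, n, replace = TRUE))
  cd3 <- pmax(0L, cd3)
  cd68_lining <- sample(0:4, n, replace = TRUE, prob = c(0.1, 0.25, 0.3, 0.25, 0.1))
  cd68_sublining <- pmax(0L, pmin(4L, cd68_lining + sample(-1:1, n, replace = TRUE)))
  cd138 <- pmax(0L, pmin(4L, cd20 + sample(-1:1, n, replace = TRUE)))
  hist_label <- classify_histology(cd20, aggregates, cd21, gradable)

  # --- site and randomization ---------------------------------------
  k <- length(config$site_labels)
  site_prob <- if (k == 1) 1 else
    c(config$prop_first_site, rep((1 - config$prop_first_site) / (k - 1), k - 1))
  site <- sample(config$site_labels, n, replace = TRUE, prob = site_prob)
  rnd <- block_randomize(make_stratum(hist_label, site))
  treatment <- as.character(rnd$assignments)

  # --- baseline visit ------------------------------------------------
  tjc0 <- pmin(28L, pmax(1L, stats::rnbinom(n, mu = 12.5, size = 3) + 1L))
  sjc0 <- pmin(28L, pmax(1L, stats::rnbinom(n, mu = 7, size = 3) + 1L))
  pga0 <- 10 * stats::rbeta(n, 6.5, 3.5)
  ega0 <- 10 * stats::rbeta(n, 5.5, 4.5)
  esr0 <- pmin(140, pmax(2, exp(stats::rnorm(n, log(31), 0.77))))
  crp0 <- pmin(300, exp(stats::rnorm(n, log(11), 1.25)))
  haq0 <- pmin(3, pmax(0.1, stats::rnorm(n, 1.7, 0.6)))
  facit0 <- pmin(52, pmax(0, stats::rnorm(n, 20, 8)))
  pcs0 <- stats::rnorm(n, 30, 7)
  mcs0 <- stats::rnorm(n, 40, 10)
  cdai0 <- tjc0 + sjc0 + pga0 + ega0

  # --- populations, response, week 16 -------------------------------
  dosed <- stats::runif(n) >= config$not_dosed_rate
  violation <- stats::runif(n) < config$violation_rate
  rate <- mapply(function(arm, cls) config$response_rates[[arm]][[cls]],
                 treatment, latent)
  responder <- dosed & (stats::runif(n) < rate)
  dropout <- !dosed | stats::runif(n) < config$dropout_rate

  f <- ifelse(responder, stats::runif(n, 0.5, 0.9), stats::runif(n, 0.05, 0.45))
  shrink <- 1 - f
  tjc1 <- as.integer(ifelse(responder, floor(tjc0 * shrink),
                            ceiling(tjc0 * shrink)))
  sjc1 <- as.integer(ifelse(responder, floor(sjc0 * shrink),
                            ceiling(sjc0 * shrink)))
  pga1 <- pga0 * shrink
  ega1 <- ega0 * shrink
  esr1 <- pmax(1, esr0 * (1 - 0.75 * f) * exp(stats::rnorm(n, 0, 0.15)))
  crp1 <- pmax(0, crp0 * (1 - 0.85 * f) * exp(stats::rnorm(n, 0, 0.2)))
  haq1 <- pmax(0, haq0 - 0.8 * f + stats::rnorm(n, 0, 0.15))
  facit1 <- pmin(52, pmax(0, facit0 + 10 * f + stats::rnorm(n, 0, 2)))
  pcs1 <- pcs0 + 8 * f + stats::rnorm(n, 0, 2)
  mcs1 <- mcs0 + 6 * f + stats::rnorm(n, 0, 2.5)

  # item-level MAR gaps conditional on baseline severity
  miss_p <- if (config$missing_rate == 0) rep(0, n) else
    stats::plogis(stats::qlogis(config$missing_rate) + 0.04 * (cdai0 - 30))
  gap <- function(x) ifelse(stats::runif(n) < miss_p, NA_real_, x)
  esr1 <- gap(esr1); crp1 <- gap(crp1); haq1 <- gap(haq1)
  facit1 <- gap(facit1); pcs1 <- gap(pcs1); mcs1 <- gap(mcs1)

  wk16 <- data.frame(wk16_tjc28 = tjc1, wk16_sjc28 = sjc1,
                     wk16_pga = pga1, wk16_ega = ega1,
                     wk16_pga_vas100 = 10 * pga1,
                     wk16_esr = esr1, wk16_crp = crp1, wk16_haq = haq1,
                     wk16_facit = facit1, wk16_sf36_pcs = pcs1,
                     wk16_sf36_mcs = mcs1)
  wk16[dropout, ] <- NA

  rf <- stats::runif(n) < ifelse(latent == "rich", 0.77, 0.70)
  acpa <- stats::runif(n) < ifelse(latent == "rich", 0.78, 0.77)
  rna_qc_pass <- stats::runif(n) >= config$rna_qc_fail_rate

  patients <- data.frame(
    patient_id = sprintf("PT%04d", seq_len(n)),
    site = site, latent_class = latent, treatment = treatment,
    cd20 = cd20, cd3 = cd3, cd68_lining = cd68_lining,
    cd68_sublining = cd68_sublining, cd138 = cd138,
    cd20_aggregates = aggregates, cd21_fdc_networks = cd21,
    tissue_gradable = gradable,
    histology_label = as.character(hist_label),
    rf_pos = rf, acpa_pos = acpa,
    dosed = dosed, protocol_violation = violation,
    rna_qc_pass = rna_qc_pass,
    responder = responder, dropout = dropout,
    bl_tjc28 = tjc0, bl_sjc28 = sjc0, bl_pga = pga0, bl_ega = ega0,
    bl_pga_vas100 = 10 * pga0, bl_esr = esr0, bl_crp = crp0,
    bl_haq = haq0, bl_facit = facit0, bl_sf36_pcs = pcs0,
    bl_sf36_mcs = mcs0,
    stringsAsFactors = FALSE
  )
  patients <- cbind(patients, wk16)

  expr <- NULL
  gene_sets <- list()
  if (expression) {
    g <- config$n_genes
    gene_ids <- sprintf("GENE%05d", seq_len(g))
    mu_g <- exp(stats::rnorm(g, log(50), 1.5))
    lib <- exp(stats::rnorm(n, 0, 0.25))
    module_idx <- seq_len(config$module_size)
    activity <- config$module_log_fold_change * (latent == "rich") +
      stats::rnorm(n, 0, config$module_sample_sd)
    mu <- outer(mu_g, lib)
    mu[module_idx, ] <- mu[module_idx, , drop = FALSE] *
      rep(2^activity, each = config$module_size)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nrow = g,
                     dimnames = list(gene_ids, patients$patient_id))
    expr <- list(counts = counts, gene_ids = gene_ids,
                 sample_ids = patients$patient_id)
    gene_sets <- list(bcell_module = gene_ids[module_idx])
  }

  structure(list(patients = patients, expression = expr,
                 gene_sets = gene_sets, config = config),
            class = "trial_dataset")
}

#' Per-patient composite indices and endpoint flags
#'
#' Recomputes CDAI and DAS28 at baseline and week 16 from the visit
#' components stored in a patients table and appends the binary endpoint
#' flags. Patients with a missing week-16 visit (or missing ESR/CRP
#' items) get `NA` for the affected week-16 indices and flags.
#'
#' @param patients a `trial_dataset$patients`-shaped `data.frame`.
#' @return The input with columns `bl_cdai`, `wk16_cdai`, `bl_das28_esr`,
#'   `wk16_das28_esr`, `bl_das28_crp`, `wk16_das28_crp` and the
#'   [endpoint_flags()] columns appended.
#' @export
compute_indices <- function(patients) {
  p <- patients
  p$bl_cdai <- cdai(p$bl_tjc28, p$bl_sjc28, p$bl_pga, p$bl_ega)
  p$wk16_cdai <- cdai(p$wk16_tjc28, p$wk16_sjc28, p$wk16_pga, p$wk16_ega)
  p$bl_das28_esr <- das28(p$bl_tjc28, p$bl_sjc28, p$bl_esr,
                          p$bl_pga_vas100, "esr")
  p$wk16_das28_esr <- das28(p$wk16_tjc28, p$wk16_sjc28, p$wk16_esr,
                            p$wk16_pga_vas100, "esr")
  p$bl_das28_crp <- das28(p$bl_tjc28, p$bl_sjc28, p$bl_crp,
                          p$bl_pga_vas100, "crp")
  p$wk16_das28_crp <- das28(p$wk16_tjc28, p$wk16_sjc28, p$wk16_crp,
                            p$wk16_pga_vas100, "crp")
  cbind(p, endpoint_flags(p$bl_cdai, p$wk16_cdai,
                          p$bl_das28_esr, p$wk16_das28_esr,
                          p$bl_das28_crp, p$wk16_das28_crp))
}

#' Molecular pathotype labels for a simulated dataset
#'
#' Runs the expression pipeline of a `trial_dataset`: size factors,
#' variance-stabilising transform, module score, then the median-cutoff
#' classification. Mirroring the trial's sample flow, patients
#' histologically classified germinal-centre positive are removed before
#' the median is computed, as are RNA-QC failures and never-dosed
#' patients; excluded patients receive `NA`.
#'
#' @param dataset a `trial_dataset` with expression present.
#' @param gene_set gene ids of the module; defaults to the dataset's
#'   `bcell_module` set.
#' @return Character vector of labels (`bcell_poor` / `bcell_rich` /
#'   `NA`) aligned with `dataset$patients`, with the module score as
#'   attribute `score` and the cutoff as attribute `cutoff`.
#' @export
molecular_labels <- function(dataset, gene_set = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (is.null(dataset$expression))
    stop("dataset has no expression matrix")
  if (is.null(gene_set)) gene_set <- dataset$gene_sets$bcell_module
  p <- dataset$patients
  eligible <- p$dosed & p$rna_qc_pass & p$histology_label != "gc_positive"
  counts <- dataset$expression$counts[, eligible, drop = FALSE]
  tr <- vst_transform(counts)
  sc <- module_score(tr, gene_set, module_name = "bcell_module")
  lab <- classify_molecular(sc$score)
  out <- rep(NA_character_, nrow(p))
  out[eligible] <- as.character(lab)
  score_full <- rep(NA_real_, nrow(p))
  score_full[eligible] <- sc$score
  structure(out, score = score_full, cutoff = attr(lab, "cutoff"))
}
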