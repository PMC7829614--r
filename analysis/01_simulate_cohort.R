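#!/usr/bin/env Rscript
# Stage 1 — generate the reference synthetic cohort.
#
# Builds one fully specified synthetic trial under the default study
# conditions (160 randomized patients, 45% latently B-cell rich, a
# 73-gene module elevated 4-fold in rich synovium, poor-stratum response
# rates 20% vs 55%) and writes it, plus a ground-truth summary, under
# results/. Everything downstream reads this directory.

suppressPackageStartupMessages(library(pathotrial))

out <- "results/cohort"
cfg <- sim_config(seed = 20260101)
ds <- simulate_trial(cfg)

# persist the clinical and histology tables only: the expression matrix
# is a deterministic function of the seed and is re-derived by the later
# stages, so the checked-in results stay small
ds_persist <- ds
ds_persist$expression <- NULL
write_dataset(ds_persist, out, overwrite = TRUE)
write_gmt(ds$gene_sets, file.path(out, "gene_sets.gmt"))

p <- ds$patients
summary_tab <- data.frame(
  n_randomized = nrow(p),
  n_itt = sum(p$dosed),
  n_latent_rich = sum(p$latent_class == "rich"),
  n_hist_poor = sum(p$histology_label == "bcell_poor"),
  n_hist_rich = sum(p$histology_label == "bcell_rich"),
  n_hist_gc = sum(p$histology_label == "gc_positive"),
  n_hist_unknown = sum(p$histology_label == "unknown"),
  n_dropout = sum(p$dropout)
)
dir.create("results", showWarnings = FALSE)
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)

cat("Synthetic cohort written to", out, "\n")
cat(sprintf("Randomized %d patients; histology split %d poor / %d rich / %d GC+ / %d unknown.\n",
            summary_tab$n_randomized, summary_tab$n_hist_poor,
            summary_tab$n_hist_rich, summary_tab$n_hist_gc,
            summary_tab$n_hist_unknown))
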