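#!/usr/bin/env Rscript
# Stage 5 — regression against the published counts.
#
# Every endpoint row of the published 16-week and safety tables whose
# four counts are printed is recomputed from scratch (risk difference,
# Wald interval, chi-squared/Fisher selection) and compared with the
# printed whole-percent values. Printed tables are not perfectly
# consistent with any single rounding rule, so both exact and
# within-one-point agreement are reported per row.

suppressPackageStartupMessages(library(pathotrial))

rp <- reproduce_printed_stats()
dir.create("results", showWarnings = FALSE)
write.csv(rp, "results/published_checks.csv", row.names = FALSE)

cat(sprintf("%d rows recomputed: %d exact, %d within one point.\n",
            nrow(rp), sum(rp$match_exact), sum(rp$match_within_1)))
off <- rp[!rp$match_exact, "row_id"]
if (length(off)) {
  cat("Rows off by one display point (documented printing inconsistencies):\n")
  cat(paste(" -", off), sep = "\n")
}
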