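#!/usr/bin/env Rscript
# Step 1 — simulate the study cohorts.
#
# Two synthetic cutaneous-melanoma cohorts stand in for the discovery and
# replication datasets: 25 UV-mutant and 25 non UV-mutant samples each,
# 8,000 array probes with ten planted DMRs (5 CpGs, |delta-beta| = 0.15),
# UV-like SBS96 mutation catalogs, methylation-coupled expression, sparse
# CNV/mutation matrices and exponential survival. Ground truth is written
# alongside so later steps can score themselves.

suppressMessages(library(melomics))

dir.create("results", showWarnings = FALSE)
for (cohort in c("discovery", "replication")) {
  seedv <- if (cohort == "discovery") 11L else 22L
  cfg <- cohort_config(seed = seedv, n_probes = 8000, n_genes = 300)
  co <- generate_cohort(cfg)
  out <- file.path("results", paste0("cohort_", cohort))
  manifest <- write_cohort(co, out)
  cat(sprintf("[%s] %d samples, %d probes, %d mutation records -> %s (%d files)\n",
              cohort, nrow(co$clinical), nrow(co$beta), nrow(co$mutations),
              out, nrow(manifest)))
}
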