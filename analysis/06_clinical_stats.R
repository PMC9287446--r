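#!/usr/bin/env Rscript
# Step 6 — clinical statistics.
#
# Reproduces the published contingency statistics from the packaged
# cohort-characteristics counts, evaluates the design power statement,
# and runs melanoma-specific survival on the simulated cohort: UV-mutant
# vs non UV-mutant curves, and survival split by mean-dichotomized
# methylation at a top prioritized CpG.

suppressMessages(library(melomics))

## published contingency tables ------------------------------------------
tabs <- table1_contingency_tables()
for (nm in c("tumor_type", "molecular_group", "uv_signature")) {
  ct <- chi_square_test(tabs[[nm]])
  cat(sprintf("%-16s chi-square %.2f (df %d), p = %.3g\n",
              nm, ct$statistic, ct$df, ct$p_value))
}

## power -----------------------------------------------------------------
pow <- power_two_sample(n = 20, delta = 0.10, sd = 0.11, alpha = 0.05)
cat(sprintf("power (n=20/group, delta=0.10, sd=0.11): %.1f%%\n", 100 * pow))

## survival by UV status --------------------------------------------------
co <- read_cohort("results/cohort_discovery")
cl <- co$clinical
lr <- logrank_test(cl$surv_months, cl$event, cl$group)
km <- km_estimate(cl$surv_months, cl$event, cl$group)
med <- vapply(split(km$table, km$table$group), function(t)
  t$time[which(t$surv <= 0.5)[1]], numeric(1))
cat(sprintf("survival UV vs non-UV: log-rank chi-square %.1f, p = %.3g; median months uv %.0f vs nonuv %.0f\n",
            lr$statistic, lr$p_value, med["uv"], med["nonuv"]))

## survival by methylation at a prioritized CpG ---------------------------
dmr <- utils::read.delim("results/dmr_discovery.tsv",
                         stringsAsFactors = FALSE)
dmp <- utils::read.delim("results/dmp_discovery.tsv",
                         stringsAsFactors = FALSE)
top_probe <- dmp$probe_id[which.min(dmp$p)]
grp <- suppressMessages(dichotomize_by_mean(co$beta[top_probe, ]))
lr2 <- logrank_test(cl$surv_months, cl$event, as.character(grp))
cat(sprintf("survival by %s methylation (low/high at the mean): log-rank p = %.3g\n",
            top_probe, lr2$p_value))

## gene-set enrichment adjusted for probes per gene ------------------------
sig_cpgs <- dmp$probe_id[dmp$q < 0.05]
planted_genes <- unique(co$annotation$gene[match(unlist(
  jsonlite::read_json("results/cohort_discovery/truth.json",
                      simplifyVector = TRUE)$dmrs$probes),
  co$annotation$probe_id)])
sets <- list(planted = planted_genes,
             random = sample(unique(co$annotation$gene), 20))
gse <- geneset_enrichment_adjusted(sig_cpgs, co$annotation, sets,
                                   B = 1000, seed = 6)
print(gse)
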