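#!/usr/bin/env Rscript
# Step 5 — cross-omics integration on the discovery cohort.
#
# eQTM correlation at the planted couplings; the four-layer cancer driver
# score over the eQTM genes plus a background sample; MAD filtering and
# PLS-DA of the methylome vs the transcriptome; sparse PLS-DA selecting
# the 25 most informative features per block; simplified block
# integration; and hierarchical clustering with non-UV cluster
# enrichment.

suppressMessages(library(melomics))
set.seed(5)

co <- read_cohort("results/cohort_discovery")
truth <- co$truth
labels <- co$clinical$group
beta <- clip_beta(co$beta)

## eQTM ------------------------------------------------------------------
tr <- truth$eqtm
eq <- eqtm_correlate(beta, co$expression,
                     data.frame(cpg = tr$cpg, gene = tr$gene))
utils::write.table(eq, "results/eqtm.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("eQTM: %d/%d planted couplings at FDR<0.05 (all r < 0: %s)\n",
            sum(eq$q < 0.05), nrow(eq), all(eq$r < 0)))

## driver score ----------------------------------------------------------
uv_status <- setNames(labels == "uv", co$clinical$sample)
genes <- unique(c(tr$gene, rownames(co$expression)[1:20]))
ann <- co$annotation
map <- data.frame(cpg = ann$probe_id, gene = ann$gene,
                  stringsAsFactors = FALSE)
ds <- driver_scores(co$cnv, co$gene_mutations, co$expression, beta, map,
                    uv_status, genes)
utils::write.table(ds, "results/driver_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("driver scores: top gene %s (total %.2f); range %.2f-%.2f over %d genes\n",
            ds$gene[1], ds$total[1], min(ds$total), max(ds$total),
            nrow(ds)))

## PLS-DA per block, sparse selection, integration ------------------------
meth_top <- mad_filter(beta, 100)
expr_top <- mad_filter(co$expression, 100)
acc_meth <- plsda_accuracy(plsda_fit(meth_top, labels))
acc_expr <- plsda_accuracy(plsda_fit(expr_top, labels))
cat(sprintf("PLS-DA training accuracy: methylome %.2f vs transcriptome %.2f\n",
            acc_meth, acc_expr))

integ <- integrate_blocks(list(meth = meth_top, expr = expr_top), labels,
                          keep = 25)
cat(sprintf("integration: %d + %d selected features, accuracy %.2f\n",
            length(integ$selections$meth), length(integ$selections$expr),
            plsda_accuracy(integ$model)))

## clustering ------------------------------------------------------------
hc <- hier_cluster(meth_top, n_clusters = 3)
enr <- cluster_enrichment(hc$clusters, labels,
                          target_clusters = which.max(vapply(1:3, function(k)
                            mean(labels[hc$clusters == k] == "nonuv"),
                            numeric(1))))
cat(sprintf("non-UV enrichment in the most non-UV cluster: chi-square %.1f, p %.3g\n",
            enr$statistic, enr$p_value))
utils::write.table(data.frame(sample = names(hc$clusters),
                              cluster = hc$clusters),
                   "results/clusters.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
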