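# melomics

Multi-omics analysis of UV mutational signatures and the DNA methylome
in melanoma.

## The problem

Cutaneous melanomas split into **UV-mutant** and **non UV-mutant**
tumours according to whether their somatic mutation catalog is dominated
by the ultraviolet signature — C>T transitions at dipyrimidine sites and
tandem CC>TT substitutions, the products of UV photodamage. That split
matters clinically (UV-mutant patients fare better) and biologically:
it is mirrored in the DNA methylome, the transcriptome and the
copy-number landscape. This package implements, as tested and reusable
R functions, the full analysis chain for studying that mirror:

- **UV signature calling** from SBS96 mutation spectra: a sample is
  UV-mutant when C>T at dipyrimidine sites exceeds 60% of the total
  mutation burden or CC>TT events exceed 5%, with NMF consensus
  extraction and cosine matching (similarity > 0.8) as confirmation.
- **Differential methylation**: per-CpG Huber-robust regression of
  M-values (`M = log2(β/(1−β))`) on UV status, genomic-inflation QC
  (λ = median χ²₁ / 0.4549), proximity-chained DMR calling within
  ±1000 bp with a Brown-corrected Stouffer combiner
  `Z = Σzᵢ / √(n + n(n−1)·r̄)`, and the prioritization cascade
  (≥ 3 CpGs, consistent direction, |Δβ| ≥ 0.10, not SNP-enriched).
- **Meta-analysis**: fixed-effects inverse-variance pooling
  (`w = 1/SE²`), FDR and Bonferroni, direction concordance, overlap
  enrichment.
- **Cross-omics**: eQTM Pearson correlation; a four-layer cancer driver
  score (CNV + MUT + EXP + METH, each max-normalized to [0,1], total in
  [0,4]); MAD filtering; PLS-DA and sparse PLS-DA (exactly 25 features
  per component); simplified block integration; hierarchical clustering.
- **Clinical statistics**: uncorrected chi-square / Fisher contingency
  tests, Mann–Whitney, Kaplan–Meier + log-rank, mean-cutoff
  dichotomization, noncentral-t power, and gene-set enrichment adjusted
  for probes-per-gene bias by matched resampling.
- **A synthetic multi-omics cohort generator** with planted ground truth
  (bimodal beta values, planted DMRs, UV-like spectra, coupled
  expression, survival), so every stage above is testable offline.

See `vignettes/melomics-methods.Rmd` for the models, parameter choices
and limitations.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step
1 simulates two 50-sample cohorts with ten planted DMRs (Δβ = ±0.15,
5 CpGs) and writes them under `results/`; the later steps analyse them:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_uv_signature.R
Rscript analysis/03_differential_methylation.R
Rscript analysis/04_meta_analysis.R
Rscript analysis/05_multiomics_integration.R
Rscript analysis/06_clinical_stats.R
```

Output of the run (abridged):

```
[discovery] rule-based calls: sensitivity 1.000, specificity 1.000; consensus cosine to UV profile 0.997
[discovery] lambda 1.012 | 55 DMPs (FDR<0.05) | 10 DMRs -> 10 prioritized | 10/10 planted recovered
pooled 56 loci | FDR<0.05: 52 | Bonferroni<0.05: 50 | same direction: 96.4%
eQTM: 5/5 planted couplings at FDR<0.05 (all r < 0: TRUE)
PLS-DA training accuracy: methylome 1.00 vs transcriptome 1.00
survival UV vs non-UV: log-rank chi-square 5.8, p = 0.0161; median months uv 38 vs nonuv 15
tumor_type       chi-square 6.75 (df 1), p = 0.00938
power (n=20/group, delta=0.10, sd=0.11): 80.0%
```

Reading this: the rule-based caller recovers every simulated UV-mutant
catalog; the methylome scan is calibrated (λ ≈ 1 on top of planted
signal), finds all ten planted regions, and they survive the
prioritization cascade; cross-cohort pooling at the planted loci gains
power and keeps direction concordance high; the planted
methylation→expression couplings are all detected with the expected
negative sign; and the clinical layer reproduces the published
contingency statistics and the design power statement from the packaged
cohort-characteristics counts (`inst/extdata/table1_counts.yaml`).

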