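# Shared fixtures, generated in code at test time.

no_dmr_specs <- function() {
  data.frame(chrom = character(0), start = numeric(0), n_cpgs = integer(0),
             spacing = numeric(0), delta_beta = numeric(0))
}

no_eqtm <- function() {
  data.frame(gene = character(0), slope = numeric(0))
}

# small planted cohort reused across files (lazily computed once)
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- cohort_config(seed = 42, n_probes = 3000, n_genes = 100)
    .fixture_env$small <- generate_cohort(cfg)
  }
  .fixture_env$small
}

small_null_cohort <- function() {
  if (is.null(.fixture_env$null)) {
    cfg <- cohort_config(seed = 43, n_probes = 3000, n_genes = 100,
                         dmr_specs = no_dmr_specs(), eqtm_genes = no_eqtm())
    .fixture_env$null <- generate_cohort(cfg)
  }
  .fixture_env$null
}

# mutation records for a single synthetic sample, channels chosen directly
make_records <- function(channels, sample = "S1", chrom = "chr1",
                         start_pos = 1000L, gap = 10L) {
  n <- length(channels)
  if (n == 0) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), context = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  ref <- substr(channels, 3, 3)
  alt <- substr(channels, 5, 5)
  ctx <- paste0(substr(channels, 1, 1), ref, substr(channels, 7, 7))
  data.frame(sample = sample, chrom = chrom,
             pos = start_pos + gap * seq_len(n), ref = ref, alt = alt,
             context = ctx, class = "SNV", stringsAsFactors = FALSE)
}
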