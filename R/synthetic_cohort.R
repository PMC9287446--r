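#' Configuration for a synthetic multi-omics melanoma cohort
#'
#' Bundles and validates every generator parameter. The defaults are the
#' package's stated study conditions (see the methods vignette): two groups
#' of 25 samples, 20,000 array probes whose baseline betas follow a
#' two-component logit-normal mixture (modes ~0.10 and ~0.85, SD 0.5 on the
#' M scale, weight 0.5), planted DMRs of 5 CpGs at delta-beta +/-0.15,
#' UV-sample SBS96 catalogs drawn from a mixture of the shipped UV-like
#' profile (weight 0.9) and a flat background with a 5% CC>TT share,
#' negative-binomial expression coupled to methylation for the eQTM genes,
#' sparse CNV and gene-mutation matrices, and exponential survival with
#' group hazards.
#'
#' @param seed Integer master seed; fixed offsets derive independent
#'   sub-streams for the methylation, mutation, expression, copy-number and
#'   survival layers, so changing one layer's parameters does not perturb
#'   the others.
#' @param n_uv,n_nonuv Samples per group.
#' @param n_probes,n_genes Array probes and genes.
#' @param dmr_specs Data frame of planted regions: `chrom`, `start`,
#'   `n_cpgs`, `spacing` (bp between consecutive CpGs), `delta_beta`
#'   (signed UV minus non-UV effect, in (-1, 1)). `NULL` plants the default
#'   ten 5-CpG regions at +/-0.15; a zero-row data frame plants none.
#' @param uv_signature_weight Fraction of each UV sample's SNVs drawn from
#'   the UV-like channel profile (the rest are flat background).
#' @param cctt_rate Fraction of each UV sample's burden emitted as CC>TT
#'   tandem DNPs.
#' @param burden_mean_uv,burden_mean_nonuv Poisson mean mutation burdens.
#' @param eqtm_genes Data frame of couplings: `gene`, `slope` (log2
#'   expression units per unit beta). `NULL` couples 5 genes at slope -3;
#'   zero rows couples none.
#' @param hazard_uv,hazard_nonuv Exponential hazards, events per month.
#' @param censor_rate Expected fraction of samples censored.
#' @param beta_modes,beta_m_sd,beta_mix_weight Baseline beta mixture: modes
#'   on the beta scale, per-sample SD on the M scale, low-mode weight.
#' @param dmr_baseline_beta Baseline beta at planted DMR probes
#'   (mid-methylated so shifted group means stay well inside (0, 1)).
#' @param nb_size Negative-binomial size (dispersion) of expression counts.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_uv = 25L, n_nonuv = 25L,
                          n_probes = 20000L, n_genes = 500L,
                          dmr_specs = NULL,
                          uv_signature_weight = 0.9,
                          cctt_rate = 0.05,
                          burden_mean_uv = 500, burden_mean_nonuv = 200,
                          eqtm_genes = NULL,
                          hazard_uv = 0.015, hazard_nonuv = 0.04,
                          censor_rate = 0.3,
                          beta_modes = c(0.10, 0.85),
                          beta_m_sd = 0.5,
                          beta_mix_weight = 0.5,
                          dmr_baseline_beta = 0.40,
                          nb_size = 20) {
  if (is.null(dmr_specs)) dmr_specs <- default_dmr_specs()
  if (is.null(eqtm_genes)) {
    eqtm_genes <- data.frame(gene = sprintf("g%04d", 1:5), slope = -3)
  }
  stopifnot(
    length(seed) == 1, seed == as.integer(seed),
    n_uv > 0, n_nonuv > 0, n_probes > 0, n_genes > 0,
    is.data.frame(dmr_specs),
    uv_signature_weight >= 0, uv_signature_weight <= 1,
    cctt_rate >= 0, cctt_rate < 1,
    burden_mean_uv > 0, burden_mean_nonuv > 0,
    hazard_uv > 0, hazard_nonuv > 0,
    censor_rate >= 0, censor_rate < 1,
    beta_m_sd > 0, all(beta_modes > 0 & beta_modes < 1),
    dmr_baseline_beta > 0, dmr_baseline_beta < 1, nb_size > 0
  )
  if (nrow(dmr_specs) > 0) {
    stopifnot(all(c("chrom", "start", "n_cpgs", "spacing", "delta_beta")
                  %in% names(dmr_specs)),
              all(abs(dmr_specs$delta_beta) < 1),
              all(dmr_specs$n_cpgs >= 1), all(dmr_specs$spacing > 0),
              all(dmr_specs$start > 0))
  }
  structure(list(seed = as.integer(seed), n_uv = as.integer(n_uv),
                 n_nonuv = as.integer(n_nonuv),
                 n_probes = as.integer(n_probes),
                 n_genes = as.integer(n_genes),
                 dmr_specs = dmr_specs,
                 uv_signature_weight = uv_signature_weight,
                 cctt_rate = cctt_rate,
                 burden_mean_uv = burden_mean_uv,
                 burden_mean_nonuv = burden_mean_nonuv,
                 eqtm_genes = eqtm_genes,
                 hazard_uv = hazard_uv, hazard_nonuv = hazard_nonuv,
                 censor_rate = censor_rate,
                 beta_modes = beta_modes, beta_m_sd = beta_m_sd,
                 beta_mix_weight = beta_mix_weight,
                 dmr_baseline_beta = dmr_baseline_beta,
                 nb_size = nb_size),
            class = "cohort_config")
}

#' Default planted DMR layout
#'
#' Ten regions of five CpGs spaced 400 bp apart, alternating
#' hyper-/hypomethylation at |delta-beta| = 0.15, spread over chr1-chr5.
#'
#' @param delta Absolute planted effect.
#' @param n_cpgs,spacing Region geometry.
#' @param n_dmrs Number of regions.
#' @return Data frame usable as `dmr_specs` in [cohort_config()].
#' @export
default_dmr_specs <- function(delta = 0.15, n_cpgs = 5L, spacing = 400L,
                              n_dmrs = 10L) {
  data.frame(
    chrom = paste0("chr", rep_len(1:5, n_dmrs)),
    start = 1e6 + 5e5 * (seq_len(n_dmrs) - 1),
    n_cpgs = n_cpgs,
    spacing = spacing,
    delta_beta = delta * rep_len(c(1, -1), n_dmrs)
  )
}

#' Read a cohort configuration from YAML
#'
#' All scalar fields of [cohort_config()] may appear at top level;
#' `dmr_specs` and `eqtm_genes` as lists of records.
#'
#' @param path YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$dmr_specs)) {
    y$dmr_specs <- do.call(rbind, lapply(y$dmr_specs, as.data.frame))
  }
  if (!is.null(y$eqtm_genes)) {
    y$eqtm_genes <- do.call(rbind, lapply(y$eqtm_genes, as.data.frame))
  }
  do.call(cohort_config, y)
}

# Fixed seed offsets: one master seed drives independent layer sub-streams.
.layer_seed <- function(config, layer) {
  off <- c(design = 101L, methylation = 1009L, mutation = 2003L,
           expression = 3001L, cnv = 4001L, survival = 5003L)
  (config$seed * 7L + off[[layer]]) %% .Machine$integer.max
}

#' Generate a synthetic multi-omics melanoma cohort
#'
#' Produces clinical labels, a beta-value matrix with planted DMRs, probe
#' annotation, SBS96 mutation catalogs mixing a UV-like and a flat profile,
#' methylation-coupled negative-binomial expression, sparse CNV and
#' gene-mutation matrices, exponential survival, and a ground-truth record
#' enabling parameter-recovery tests. Identical configurations generate
#' identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return Object of class `multiomics_cohort`: list with `clinical`,
#'   `beta`, `annotation`, `expression`, `cnv`, `gene_mutations`,
#'   `mutations`, `truth` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_uv + config$n_nonuv
  samples <- sprintf("S%03d", seq_len(n))
  group <- c(rep("uv", config$n_uv), rep("nonuv", config$n_nonuv))

  set.seed(.layer_seed(config, "design"))
  clinical <- data.frame(
    sample = samples,
    group = group,
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4)),
    age = round(stats::rnorm(n, 57, 15)),
    tumor_type = sample(c("primary", "metastatic"), n, replace = TRUE,
                        prob = c(0.3, 0.7)),
    stringsAsFactors = FALSE
  )

  probes <- .generate_probes(config)
  annotation <- probes$annotation
  truth_dmrs <- probes$truth_dmrs

  set.seed(.layer_seed(config, "methylation"))
  beta <- .generate_beta(config, annotation, truth_dmrs, group, samples)

  set.seed(.layer_seed(config, "mutation"))
  mutations <- .generate_mutations(config, samples, group)

  set.seed(.layer_seed(config, "expression"))
  expr <- .generate_expression(config, annotation, truth_dmrs, beta, samples)

  set.seed(.layer_seed(config, "cnv"))
  genes <- rownames(expr$expression)
  cnv <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), config$n_genes * n,
                       replace = TRUE, prob = c(0.03, 0.07, 0.80, 0.07, 0.03)),
                config$n_genes, n, dimnames = list(genes, samples))
  p_mut <- stats::runif(config$n_genes, 0.02, 0.30)
  gene_mutations <- matrix(stats::rbinom(config$n_genes * n, 1L,
                                         rep(p_mut, n)),
                           config$n_genes, n, dimnames = list(genes, samples))

  set.seed(.layer_seed(config, "survival"))
  hz <- ifelse(group == "uv", config$hazard_uv, config$hazard_nonuv)
  t_event <- stats::rexp(n, rate = hz)
  if (config$censor_rate > 0) {
    cr <- config$censor_rate
    t_cens <- stats::rexp(n, rate = hz * cr / (1 - cr))
  } else {
    t_cens <- rep(Inf, n)
  }
  clinical$surv_months <- round(pmin(t_event, t_cens), 2)
  clinical$event <- as.integer(t_event <= t_cens)

  truth <- list(dmrs = truth_dmrs, eqtm = expr$truth_eqtm,
                uv_status = stats::setNames(group == "uv", samples))

  structure(list(clinical = clinical, beta = beta, annotation = annotation,
                 expression = expr$expression, cnv = cnv,
                 gene_mutations = gene_mutations, mutations = mutations,
                 truth = truth, config = config),
            class = "multiomics_cohort")
}

.generate_probes <- function(config) {
  set.seed(.layer_seed(config, "design") + 1L)
  specs <- config$dmr_specs
  n_planted <- if (nrow(specs) > 0) sum(specs$n_cpgs) else 0L
  if (n_planted > config$n_probes) stop("more planted CpGs than probes")
  n_bg <- config$n_probes - n_planted

  chroms <- paste0("chr", 1:22)
  bg_counts <- tabulate(sample.int(length(chroms), n_bg, replace = TRUE),
                        nbins = length(chroms))
  # clustered spacing as on the 450K array: most neighbours within a few kb
  bg_pos <- unlist(lapply(bg_counts, function(k) {
    if (k == 0) return(integer(0))
    cumsum(pmax(50L, as.integer(stats::rexp(k, 1 / 1500)))) + 10000L
  }))
  bg_chrom <- rep(chroms, bg_counts)

  planted <- NULL
  if (nrow(specs) > 0) {
    planted <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
      s <- specs[i, ]
      if (s$start + (s$n_cpgs - 1) * s$spacing > 2.5e8) {
        stop("DMR placed beyond chromosome extent")
      }
      data.frame(chrom = s$chrom,
                 pos = as.integer(s$start + (0:(s$n_cpgs - 1)) * s$spacing),
                 dmr = i, delta_beta = s$delta_beta)
    }))
    # keep background probes out of the planted windows (+/- 1001 bp)
    keep <- rep(TRUE, n_bg)
    for (i in seq_len(nrow(specs))) {
      s <- specs[i, ]
      lo <- s$start - 1001L
      hi <- s$start + (s$n_cpgs - 1) * s$spacing + 1001L
      keep <- keep & !(bg_chrom == s$chrom & bg_pos >= lo & bg_pos <= hi)
    }
    bg_chrom <- bg_chrom[keep]
    bg_pos <- bg_pos[keep]
  }

  chrom <- c(bg_chrom, if (!is.null(planted)) planted$chrom)
  pos <- c(bg_pos, if (!is.null(planted)) planted$pos)
  dmr_id <- c(rep(NA_integer_, length(bg_pos)),
              if (!is.null(planted)) planted$dmr)
  delta <- c(rep(0, length(bg_pos)), if (!is.null(planted)) planted$delta_beta)

  ord <- order(factor(chrom, levels = chroms), pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  dmr_id <- dmr_id[ord]; delta <- delta[ord]
  np <- length(pos)
  probe_id <- sprintf("cg%07d", seq_len(np))

  is_planted <- !is.na(dmr_id)
  sexp <- stats::runif(np) < 0.02 & !is_planted
  annotation <- data.frame(
    probe_id = probe_id,
    chrom = ifelse(sexp, "chrX", chrom),
    pos = pos,
    gene = sprintf("g%04d", 1 + (seq_len(np) - 1) %%
                     max(1L, config$n_genes)),
    regulatory_class = sample(c("promoter", "5'UTR", "exon/intron",
                                "1to5kb", "other"),
                              np, replace = TRUE,
                              prob = c(0.25, 0.10, 0.10, 0.15, 0.40)),
    density_class = sample(c("island", "shore", "shelf", "open sea"),
                           np, replace = TRUE,
                           prob = c(0.30, 0.25, 0.15, 0.30)),
    snp_flag = stats::runif(np) < 0.05 & !is_planted,
    cross_reactive_flag = stats::runif(np) < 0.02 & !is_planted,
    stringsAsFactors = FALSE
  )
  annotation$sex_chrom_flag <- annotation$chrom %in% c("chrX", "chrY")
  annotation$planted_dmr <- dmr_id
  annotation$planted_delta <- delta

  truth_dmrs <- NULL
  if (nrow(specs) > 0) {
    truth_dmrs <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
      memb <- annotation$probe_id[!is.na(annotation$planted_dmr) &
                                    annotation$planted_dmr == i]
      mpos <- annotation$pos[match(memb, annotation$probe_id)]
      data.frame(dmr = i, chrom = specs$chrom[i],
                 start = min(mpos), end = max(mpos),
                 n_cpgs = length(memb), delta_beta = specs$delta_beta[i],
                 probes = I(list(memb)))
    }))
  }
  list(annotation = annotation, truth_dmrs = truth_dmrs)
}

.generate_beta <- function(config, annotation, truth_dmrs, group, samples) {
  np <- nrow(annotation)
  n <- length(samples)
  low <- stats::runif(np) < config$beta_mix_weight
  base_beta <- ifelse(low, config$beta_modes[1], config$beta_modes[2])
  planted <- !is.na(annotation$planted_dmr)
  base_beta[planted] <- config$dmr_baseline_beta

  target <- matrix(rep(base_beta, n), np, n)
  if (any(planted)) {
    uv_cols <- which(group == "uv")
    target[planted, uv_cols] <- pmin(pmax(
      base_beta[planted] + annotation$planted_delta[planted], 0.001), 0.999)
  }
  m <- beta_to_m(target) + matrix(stats::rnorm(np * n, 0, config$beta_m_sd),
                                  np, n)
  beta <- m_to_beta(m)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(annotation$probe_id, samples)
  beta
}

.generate_mutations <- function(config, samples, group) {
  profile_uv <- config$uv_signature_weight * uv_signature_profile() +
    (1 - config$uv_signature_weight) * rep(1 / 96, 96)
  profile_flat <- rep(1 / 96, 96)
  channels <- sbs96_channels()

  recs <- lapply(seq_along(samples), function(j) {
    is_uv <- group[j] == "uv"
    mean_b <- if (is_uv) config$burden_mean_uv else config$burden_mean_nonuv
    burden <- stats::rpois(1, mean_b)
    if (burden == 0) return(NULL)
    n_dnp <- if (is_uv) stats::rbinom(1, burden, config$cctt_rate) else 0L
    n_snv <- burden - n_dnp
    prof <- if (is_uv) profile_uv else profile_flat
    ch <- if (n_snv > 0) sample(channels, n_snv, replace = TRUE, prob = prof)
          else character(0)
    # positions sparse over a genome-scale range: accidental adjacency ~0
    pos <- sort(sample.int(2.4e8, n_snv + n_dnp)) + 1000L
    ref <- substr(ch, 3, 3)
    alt <- substr(ch, 5, 5)
    ctx <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
    out <- data.frame(sample = samples[j], chrom = "chr1",
                      pos = pos,
                      ref = c(ref, rep("CC", n_dnp)),
                      alt = c(alt, rep("TT", n_dnp)),
                      context = c(ctx, rep("NA", n_dnp)),
                      class = c(rep("SNV", n_snv), rep("DNP", n_dnp)),
                      stringsAsFactors = FALSE)
    out$context[out$class == "DNP"] <- "CCN"
    out
  })
  do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
}

.generate_expression <- function(config, annotation, truth_dmrs, beta,
                                 samples) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  n <- length(samples)
  base <- stats::runif(config$n_genes, 5, 9)
  log2mu <- matrix(rep(base, n), config$n_genes, n,
                   dimnames = list(genes, samples))

  eq <- config$eqtm_genes
  truth_eqtm <- NULL
  if (nrow(eq) > 0) {
    # couple each eQTM gene to a planted DMR probe when available (those
    # CpGs vary between groups), else to a random clean autosomal probe
    cand <- if (!is.null(truth_dmrs)) {
      vapply(truth_dmrs$probes, function(p) p[1], character(1))
    } else character(0)
    clean <- annotation$probe_id[!annotation$snp_flag &
                                   !annotation$cross_reactive_flag &
                                   !annotation$sex_chrom_flag]
    pool <- c(cand, sample(clean, nrow(eq)))
    cpgs <- pool[seq_len(nrow(eq))]
    truth_eqtm <- data.frame(gene = eq$gene, cpg = cpgs, slope = eq$slope,
                             stringsAsFactors = FALSE)
    for (i in seq_len(nrow(eq))) {
      g <- match(eq$gene[i], genes)
      if (is.na(g)) stop("eQTM gene not in gene universe: ", eq$gene[i])
      log2mu[g, ] <- log2mu[g, ] + eq$slope[i] * beta[cpgs[i], ]
    }
  }
  counts <- matrix(stats::rnbinom(length(log2mu), mu = 2^log2mu,
                                  size = config$nb_size),
                   nrow(log2mu), ncol(log2mu), dimnames = dimnames(log2mu))
  list(expression = log2(counts + 1), truth_eqtm = truth_eqtm)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits the TSV/JSON formats consumed by the downstream modules (clinical
#' table, beta matrix at 6 decimals, probe annotation, expression, CNV,
#' gene-mutation and mutation-record tables), a `truth.json` ground-truth
#' file, and a `manifest.json` listing every emitted file with its MD5
#' checksum.
#'
#' @param cohort A `multiomics_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest as a data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "multiomics_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  w(cohort$clinical, "clinical.tsv")
  w(cohort$annotation, "probe_annotation.tsv")
  w(cohort$mutations, "mutations.tsv")
  write_matrix_tsv(round(cohort$beta, 6), file.path(dir, "beta.tsv"),
                   id_col = "probe_id")
  write_matrix_tsv(round(cohort$expression, 6),
                   file.path(dir, "expression.tsv"), id_col = "gene")
  write_matrix_tsv(cohort$cnv, file.path(dir, "cnv.tsv"), id_col = "gene")
  write_matrix_tsv(cohort$gene_mutations,
                   file.path(dir, "gene_mutations.tsv"), id_col = "gene")

  truth <- cohort$truth
  truth$uv_status <- as.list(truth$uv_status)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  files <- c("clinical.tsv", "probe_annotation.tsv", "mutations.tsv",
             "beta.tsv", "expression.tsv", "cnv.tsv", "gene_mutations.tsv",
             "truth.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(manifest)
}

#' Read back a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the emitted files.
#' @return List with the same matrix/table components (ground truth parsed
#'   from `truth.json`).
#' @export
read_cohort <- function(dir) {
  r <- function(f) utils::read.delim(file.path(dir, f),
                                     stringsAsFactors = FALSE)
  list(
    clinical = r("clinical.tsv"),
    annotation = r("probe_annotation.tsv"),
    mutations = r("mutations.tsv"),
    beta = read_matrix_tsv(file.path(dir, "beta.tsv")),
    expression = read_matrix_tsv(file.path(dir, "expression.tsv")),
    cnv = read_matrix_tsv(file.path(dir, "cnv.tsv")),
    gene_mutations = read_matrix_tsv(file.path(dir, "gene_mutations.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}

#' Write / read a matrix as TSV with an id column
#'
#' @param m Matrix with rownames.
#' @param path File path.
#' @param id_col Name of the first (row id) column.
#' @return `read_matrix_tsv` returns the numeric matrix with rownames.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
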