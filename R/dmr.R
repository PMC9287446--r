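#' Call differentially methylated regions by proximity chaining
#'
#' Probes significant at the per-CpG FDR threshold are chained per
#' chromosome while consecutive gaps stay within `max_gap` (±1000 bp by
#' default). Each chain of at least `min_cpgs` probes becomes a region
#' whose combined statistic is a Stouffer sum of the member z-scores with a
#' Brown-style correction for inter-probe correlation:
#' `Z = sum(z_i) / sqrt(n + n*(n-1)*rbar)` where `rbar` is the mean
#' pairwise correlation of the member M-values, clipped to `[0, 1)`.
#' Region p-values are two-sided normal, with Benjamini-Hochberg FDR
#' across regions. Member sets partition the significant probes: no probe
#' belongs to two regions.
#'
#' @param dmps A `dmp_result` from [fit_dmp()].
#' @param annotation Probe annotation with `probe_id`, `chrom`, `pos` and
#'   `snp_flag`.
#' @param mvalues M-value matrix used for the member correlation.
#' @param max_gap Maximum gap (bp) between consecutive member probes.
#' @param min_cpgs Minimum probes per region.
#' @param q_threshold Per-CpG FDR threshold for seeding regions.
#' @return Data frame of class `dmr_result`: `chrom`, `start`, `end`,
#'   `n_cpgs`, `z`, `p`, `q`, `mean_coef`, `se_brown`, `mean_delta_beta`,
#'   `direction_consistent`, `snp_fraction`, plus list columns `probes` and
#'   `member_delta_beta`.
#' @export
call_dmrs <- function(dmps, annotation, mvalues, max_gap = 1000L,
                      min_cpgs = 2L, q_threshold = 0.05) {
  idx <- match(dmps$probe_id, annotation$probe_id)
  if (anyNA(idx)) stop("DMP probe missing from annotation")
  d <- cbind(dmps, chrom = annotation$chrom[idx], pos = annotation$pos[idx],
             snp_flag = annotation$snp_flag[idx])
  sig <- d[!is.na(d$q) & d$q < q_threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0), z = numeric(0),
                      p = numeric(0), q = numeric(0), mean_coef = numeric(0),
                      se_brown = numeric(0), mean_delta_beta = numeric(0),
                      direction_consistent = logical(0),
                      snp_fraction = numeric(0))
  empty$probes <- list(); empty$member_delta_beta <- list()
  class(empty) <- c("dmr_result", "data.frame")
  if (nrow(sig) == 0) return(empty)

  if (is.unsorted(order(sig$chrom, sig$pos))) {
    message("call_dmrs: sorting probes by position")
  }
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  new_chain <- c(TRUE, diff(sig$pos) > max_gap |
                   sig$chrom[-1] != sig$chrom[-nrow(sig)])
  chain_id <- cumsum(new_chain)

  regions <- lapply(split(seq_len(nrow(sig)), chain_id), function(rows) {
    if (length(rows) < min_cpgs) return(NULL)
    m <- sig[rows, , drop = FALSE]
    n <- nrow(m)
    pclamp <- pmax(m$p, 1e-300)
    z <- sign(m$coef) * stats::qnorm(pclamp / 2, lower.tail = FALSE)
    rbar <- 0
    if (n > 1) {
      cm <- stats::cor(t(mvalues[m$probe_id, , drop = FALSE]))
      rbar <- mean(cm[upper.tri(cm)])
      rbar <- min(max(rbar, 0), 1 - 1e-9)
    }
    denom <- sqrt(n + n * (n - 1) * rbar)
    Z <- sum(z) / denom
    se_brown <- sqrt(sum(outer(m$se, m$se) *
                           (diag(n) + rbar * (1 - diag(n))))) / n
    data.frame(chrom = m$chrom[1], start = min(m$pos), end = max(m$pos),
               n_cpgs = n, z = Z, p = 2 * stats::pnorm(-abs(Z)),
               q = NA_real_, mean_coef = mean(m$coef), se_brown = se_brown,
               mean_delta_beta = mean(m$delta_beta),
               direction_consistent = all(m$delta_beta > 0) ||
                 all(m$delta_beta < 0),
               snp_fraction = mean(m$snp_flag),
               probes = I(list(m$probe_id)),
               member_delta_beta = I(list(m$delta_beta)),
               stringsAsFactors = FALSE)
  })
  regions <- regions[!vapply(regions, is.null, logical(1))]
  if (length(regions) == 0) return(empty)
  out <- do.call(rbind, regions)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  class(out) <- c("dmr_result", "data.frame")
  out
}

#' Prioritization filter cascade for DMRs
#'
#' Retains regions that (1) encompass at least `min_cpgs` CpGs, (2) have
#' consistent directions of effect across all member CpGs, (3) have an
#' absolute mean effect size of at least `min_abs_delta_beta` (10%
#' methylation difference), and (4) are not enriched in SNP-flagged probes
#' (member SNP fraction below `snp_fraction_max`). Per-filter attrition
#' counts are attached as attribute `"attrition"`. Tightening any
#' threshold can only remove regions.
#'
#' @param dmrs A `dmr_result` from [call_dmrs()].
#' @param min_cpgs,min_abs_delta_beta,snp_fraction_max Filter thresholds.
#' @return Filtered `dmr_result` with an `"attrition"` attribute.
#' @export
prioritize_dmrs <- function(dmrs, min_cpgs = 3L, min_abs_delta_beta = 0.10,
                            snp_fraction_max = 0.5) {
  keep1 <- dmrs$n_cpgs >= min_cpgs
  keep2 <- keep1 & dmrs$direction_consistent
  keep3 <- keep2 & abs(dmrs$mean_delta_beta) >= min_abs_delta_beta
  keep4 <- keep3 & dmrs$snp_fraction < snp_fraction_max
  attrition <- c(input = nrow(dmrs),
                 after_min_cpgs = sum(keep1),
                 after_direction = sum(keep2),
                 after_effect_size = sum(keep3),
                 after_snp = sum(keep4))
  out <- dmrs[keep4, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  class(out) <- c("dmr_result", "data.frame")
  out
}

#' Enrichment of selected probes in genomic region classes
#'
#' For each regulatory or CpG-density class, tests the 2x2 table
#' (selected vs not) x (in class vs not) against the full annotation
#' reference set with an uncorrected chi-square test, as used for the
#' hyper-/hypomethylated DMR distributions over promoters, UTRs, islands
#' and shores.
#'
#' @param selected_probes Probe ids (e.g. members of prioritized DMRs,
#'   split by effect direction by the caller).
#' @param annotation Reference probe annotation.
#' @param axis `"regulatory"` or `"density"`.
#' @return Data frame: `class`, `n_selected`, `n_reference`, `odds_ratio`,
#'   `statistic`, `p`.
#' @export
region_class_enrichment <- function(selected_probes, annotation,
                                    axis = c("regulatory", "density")) {
  axis <- match.arg(axis)
  if (length(selected_probes) == 0) stop("empty probe selection")
  if (!all(selected_probes %in% annotation$probe_id)) {
    stop("selected probes must be a subset of the annotation")
  }
  cls <- if (axis == "regulatory") annotation$regulatory_class
         else annotation$density_class
  sel <- annotation$probe_id %in% selected_probes
  res <- lapply(sort(unique(cls)), function(cl) {
    a <- sum(sel & cls == cl); b <- sum(sel & cls != cl)
    c_ <- sum(!sel & cls == cl); d <- sum(!sel & cls != cl)
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    ct <- chi_square_test(tab)
    or <- (a * d) / max(1e-12, (b * c_))
    data.frame(class = cl, n_selected = a, n_reference = a + c_,
               odds_ratio = or, statistic = ct$statistic, p = ct$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
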