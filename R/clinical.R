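#' Pearson chi-square test without continuity correction
#'
#' Uncorrected chi-square on an r x c contingency table, df = (r-1)(c-1),
#' upper-tail p-value. The uncorrected statistic is the one that
#' reproduces the published clinicopathological comparisons (tumor type,
#' molecular group, UV-signature status).
#'
#' @param table Matrix of non-negative integer counts, at least 2x2.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts")
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Fisher's exact test (2x2, two-sided)
#'
#' Two-sided p-value as the sum of hypergeometric point probabilities no
#' larger than that of the observed table — the convention used when
#' sample sizes are too small for the chi-square approximation.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return List: `p_value`, `odds_ratio`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Mann-Whitney U test
#'
#' Exact enumeration when the pooled sample size is at most 16 and there
#' are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Returns the U statistic for the first sample.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return List: `U`, `p_value`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 16) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Kaplan-Meier product-limit estimate
#'
#' Melanoma-specific survival curves per group with Greenwood standard
#' errors; at tied times events are processed before censorings (the
#' standard convention).
#'
#' @param time Follow-up in months.
#' @param event Event indicator (1 = disease-specific death).
#' @param group Optional group labels (one curve per group).
#' @return List: `table` (data frame `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, `se`), `fit` (the underlying `survfit`).
#' @export
km_estimate <- function(time, event, group = NULL) {
  stopifnot(all(time >= 0))
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep("all", length(s$time))
         else sub("^group=", "", as.character(s$strata))
  list(table = data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                          n_event = s$n.event, surv = s$surv,
                          se = s$std.err, stringsAsFactors = FALSE),
       fit = fit)
}

#' Log-rank test between survival curves
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels, at least 2 groups.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) < 2) stop("need at least 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Dichotomize values at their mean
#'
#' Labels a sample `"low"` when its value is strictly below the mean
#' across samples and `"high"` otherwise (a value exactly at the mean is
#' `"high"`). Used to split patients by CpG methylation for survival
#' analysis.
#'
#' @param values Named numeric vector (>= 2 samples).
#' @return Factor of `"low"`/`"high"` labels with group sizes reported.
#' @export
dichotomize_by_mean <- function(values) {
  if (length(values) < 2) stop("need at least 2 samples")
  if (stats::sd(values) < 1e-15) warning("constant values: all labelled high")
  lab <- factor(ifelse(values < mean(values), "low", "high"),
                levels = c("low", "high"))
  names(lab) <- names(values)
  message(sprintf("dichotomize_by_mean: %d low, %d high",
                  sum(lab == "low"), sum(lab == "high")))
  lab
}

#' Power of the two-sided two-sample t-test
#'
#' Noncentral-t power with df = 2n - 2 and noncentrality
#' `delta / (sd * sqrt(2/n))` — the calculation behind the design
#' statement that 20 cases and 20 controls give over 80% power to detect
#' a 10% methylation difference at the array-wide probe SD of 0.11.
#'
#' @param n Samples per group.
#' @param delta True mean difference (beta-value units).
#' @param sd Common standard deviation (beta-value units).
#' @param alpha Two-sided significance level.
#' @return Scalar power.
#' @export
power_two_sample <- function(n, delta, sd, alpha = 0.05) {
  stopifnot(n > 0, sd > 0, alpha > 0, alpha < 1, delta >= 0)
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tcrit <- stats::qt(1 - alpha / 2, df)
  # both rejection regions, so the null effect gives exactly alpha
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Gene-set enrichment adjusted for probes-per-gene bias
#'
#' Genes with more array probes are more likely to contain a significant
#' CpG; a naive set test is therefore biased. This test resamples, B
#' times, random gene sets matched to the target set on the decile of
#' per-gene probe count, and compares the observed number of significant
#' genes in the set with that matched null:
#' `p = (1 + #(null >= observed)) / (B + 1)`, BH-adjusted across sets.
#'
#' @param significant_cpgs Probe ids declared significant.
#' @param annotation Probe annotation with `probe_id` and `gene`.
#' @param sets Named list of gene-symbol vectors.
#' @param B Number of resamples (>= 100).
#' @param seed Seed for the resampling.
#' @return Data frame: `set`, `set_size`, `observed`, `p`, `q`.
#' @export
geneset_enrichment_adjusted <- function(significant_cpgs, annotation, sets,
                                        B = 10000L, seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  if (length(sets) == 0 || any(lengths(sets) == 0)) stop("empty gene set")
  probe_counts <- table(annotation$gene)
  universe <- names(probe_counts)
  decile <- cut(as.numeric(probe_counts),
                breaks = unique(stats::quantile(as.numeric(probe_counts),
                                                probs = seq(0, 1, 0.1))),
                include.lowest = TRUE, labels = FALSE)
  names(decile) <- universe
  sig_genes <- unique(annotation$gene[annotation$probe_id %in%
                                        significant_cpgs])
  set.seed(seed)
  res <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]], universe)
    observed <- length(intersect(genes, sig_genes))
    strata <- table(decile[genes])
    null <- vapply(seq_len(B), function(b) {
      draw <- unlist(lapply(names(strata), function(d) {
        pool <- universe[decile == as.integer(d)]
        sample(pool, min(strata[[d]], length(pool)))
      }))
      length(intersect(draw, sig_genes))
    }, numeric(1))
    data.frame(set = nm, set_size = length(genes), observed = observed,
               p = (1 + sum(null >= observed)) / (B + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Enrichment of a group within target clusters
#'
#' 2x2 chi-square of (sample in the target clusters vs not) against
#' (non-UV vs UV), delegating to [chi_square_test()] — the test used to
#' show non UV-mutant patients concentrate in the distinct methylome
#' clusters.
#'
#' @param cluster_labels Integer cluster assignment per sample.
#' @param group_labels `"uv"`/`"nonuv"` per sample.
#' @param target_clusters Clusters forming the target side of the table.
#' @return As [chi_square_test()], plus the induced `table`.
#' @export
cluster_enrichment <- function(cluster_labels, group_labels,
                               target_clusters) {
  stopifnot(length(cluster_labels) == length(group_labels))
  in_target <- cluster_labels %in% target_clusters
  nonuv <- group_labels == "nonuv"
  tab <- matrix(c(sum(in_target & nonuv), sum(in_target & !nonuv),
                  sum(!in_target & nonuv), sum(!in_target & !nonuv)),
                2, byrow = TRUE,
                dimnames = list(c("target", "other"), c("nonuv", "uv")))
  res <- chi_square_test(tab)
  res$table <- tab
  res
}

#' Published clinicopathological contingency tables
#'
#' Reads the packaged transcription of the published cohort
#' characteristics table (tumor type, molecular group and UV-signature
#' counts for the two cutaneous cohorts and the acral cohort) and returns
#' the comparison matrices.
#'
#' @param path YAML file; defaults to the packaged copy.
#' @return Named list of integer matrices.
#' @export
table1_contingency_tables <- function(path = system.file(
  "extdata", "table1_counts.yaml", package = "melomics")) {
  y <- yaml::read_yaml(path)
  lapply(y, function(tab) {
    m <- do.call(rbind, lapply(tab$rows, function(r) unlist(r$counts)))
    rownames(m) <- vapply(tab$rows, `[[`, character(1), "label")
    colnames(m) <- unlist(tab$columns)
    m
  })
}
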