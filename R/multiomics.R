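#' eQTM correlation between CpG methylation and gene expression
#'
#' Pearson correlation per (CpG, gene) pair over shared samples, two-sided
#' p-value from the t reference with n-2 degrees of freedom,
#' Benjamini-Hochberg FDR across pairs. Zero-variance vectors give a
#' flagged NA row rather than an error.
#'
#' @param beta Beta matrix, probes x samples.
#' @param expression Log2 expression matrix, genes x samples.
#' @param pairs Data frame with columns `cpg`, `gene`.
#' @return Data frame: `cpg`, `gene`, `r`, `p`, `q`, `n`.
#' @export
eqtm_correlate <- function(beta, expression, pairs) {
  shared <- intersect(colnames(beta), colnames(expression))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  stopifnot(all(pairs$cpg %in% rownames(beta)),
            all(pairs$gene %in% rownames(expression)))
  n <- length(shared)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- beta[pairs$cpg[i], shared]
    y <- expression[pairs$gene[i], shared]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      return(data.frame(cpg = pairs$cpg[i], gene = pairs$gene[i],
                        r = NA_real_, p = NA_real_, n = n))
    }
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
    data.frame(cpg = pairs$cpg[i], gene = pairs$gene[i], r = r,
               p = 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE),
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Multi-omics cancer driver score
#'
#' Per gene, four max-normalized alteration counts are summed:
#' CNV — samples with a deep amplification (call >= +2) or deep deletion
#' (call <= -2); MUT — samples with at least one mutation; EXP — UV-mutant
#' samples whose log2 expression deviates from the non-UV group mean by
#' more than `logfc_threshold` in absolute value; METH — UV-mutant samples
#' whose gene-averaged beta deviates from the non-UV group mean by more
#' than `delta_beta_threshold`. Each count is divided by the maximum count
#' over the analysed gene set, so every sub-score lies in [0, 1], the
#' layer argmax scores 1 (when the layer has any event), and the total
#' lies in [0, 4]. A gene absent from a layer scores 0 there (logged).
#'
#' @param cnv Integer CNV call matrix, genes x samples, calls in [-2, 2].
#' @param mutations 0/1 gene x sample mutation presence matrix.
#' @param expression Log2 expression matrix, genes x samples.
#' @param beta Beta matrix, probes x samples.
#' @param cpg_gene_map Data frame `cpg`, `gene` mapping probes to genes
#'   (gene-level beta is the unweighted mean over the gene's CpGs).
#' @param uv_status Named logical per sample (TRUE = UV-mutant).
#' @param genes Gene set to score.
#' @param logfc_threshold,delta_beta_threshold Event thresholds.
#' @return Data frame sorted by decreasing `total`: `gene`, `cnv_score`,
#'   `mut_score`, `exp_score`, `meth_score`, `total`, with raw counts as
#'   `*_count` columns.
#' @export
driver_scores <- function(cnv, mutations, expression, beta, cpg_gene_map,
                          uv_status, genes, logfc_threshold = 2,
                          delta_beta_threshold = 0.1) {
  stopifnot(length(genes) > 0)
  uv_ids <- names(uv_status)[uv_status]
  nonuv_ids <- names(uv_status)[!uv_status]
  if (length(uv_ids) == 0 || length(nonuv_ids) == 0) {
    stop("both UV-mutant and non UV-mutant samples are required")
  }
  count_layer <- function(gene, layer, f) {
    if (!gene %in% rownames(layer)) return(NA_integer_)
    f(layer[gene, ])
  }
  counts <- lapply(genes, function(g) {
    cnv_n <- count_layer(g, cnv, function(x) sum(abs(x) >= 2))
    mut_n <- count_layer(g, mutations, function(x) sum(x >= 1))
    exp_n <- if (g %in% rownames(expression)) {
      ref <- mean(expression[g, nonuv_ids])
      sum(abs(expression[g, uv_ids] - ref) > logfc_threshold)
    } else NA_integer_
    meth_n <- {
      cpgs <- cpg_gene_map$cpg[cpg_gene_map$gene == g]
      cpgs <- intersect(cpgs, rownames(beta))
      if (length(cpgs) == 0) NA_integer_ else {
        gb <- colMeans(beta[cpgs, , drop = FALSE])
        ref <- mean(gb[nonuv_ids])
        sum(abs(gb[uv_ids] - ref) > delta_beta_threshold)
      }
    }
    c(cnv = cnv_n, mut = mut_n, exp = exp_n, meth = meth_n)
  })
  cm <- do.call(rbind, counts)
  if (anyNA(cm)) {
    message("driver_scores: ", sum(is.na(cm)),
            " gene-layer combinations missing; scored 0")
    cm[is.na(cm)] <- 0L
  }
  norm <- apply(cm, 2, function(x) if (max(x) > 0) x / max(x) else x * 0)
  norm <- matrix(norm, ncol = 4, dimnames = dimnames(cm))
  out <- data.frame(gene = genes,
                    cnv_score = norm[, "cnv"], mut_score = norm[, "mut"],
                    exp_score = norm[, "exp"], meth_score = norm[, "meth"],
                    total = rowSums(norm),
                    cnv_count = cm[, "cnv"], mut_count = cm[, "mut"],
                    exp_count = cm[, "exp"], meth_count = cm[, "meth"],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Keep the k most variable rows by median absolute deviation
#'
#' MAD is unscaled (constant 1); ties are broken by lexicographic row
#' name, so the selection is deterministic.
#'
#' @param m Matrix with rownames.
#' @param k Number of rows to retain (`<= nrow(m)`).
#' @return Submatrix of the k highest-MAD rows.
#' @export
mad_filter <- function(m, k = 100L) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(m)) stop("k exceeds number of rows")
  madv <- apply(m, 1, stats::mad, constant = 1)
  ord <- order(-madv, rownames(m))
  m[sort(ord[seq_len(k)]), , drop = FALSE]
}
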