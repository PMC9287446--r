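#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Pools per-probe (or per-region) coefficients across studies with
#' weights `w_i = 1/SE_i^2`: pooled `b = sum(w b)/sum(w)`,
#' `SE = 1/sqrt(sum(w))`, `Z = b/SE`, two-sided normal p-values, with both
#' Benjamini-Hochberg FDR and Bonferroni adjustment. Only probes present
#' in every study are pooled; the rest are returned unpooled in the
#' `"unpooled"` attribute. Cochran's Q is reported as annotation (the
#' model itself is fixed-effects only).
#'
#' @param estimates Named list of data frames, one per study, each with
#'   columns `probe_id` (or `id`), `coef`, `se`.
#' @return Data frame: `probe_id`, `coef`, `se`, `z`, `p`, `q`,
#'   `p_bonferroni`, `n_studies`, `same_direction`, `q_cochran`,
#'   `p_cochran`.
#' @export
ivw_meta <- function(estimates) {
  stopifnot(is.list(estimates), length(estimates) >= 1)
  estimates <- lapply(estimates, function(e) {
    if ("id" %in% names(e) && !"probe_id" %in% names(e)) {
      names(e)[names(e) == "id"] <- "probe_id"
    }
    stopifnot(all(c("probe_id", "coef", "se") %in% names(e)))
    if (any(e$se <= 0 | !is.finite(e$se))) stop("non-positive SE")
    e
  })
  common <- Reduce(intersect, lapply(estimates, `[[`, "probe_id"))
  k <- length(estimates)
  B <- sapply(estimates, function(e) e$coef[match(common, e$probe_id)])
  S <- sapply(estimates, function(e) e$se[match(common, e$probe_id)])
  B <- matrix(B, ncol = k); S <- matrix(S, ncol = k)
  W <- 1 / S^2
  sw <- rowSums(W)
  b <- rowSums(W * B) / sw
  se <- 1 / sqrt(sw)
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  qc <- rowSums(W * (B - b)^2)
  sgn <- sign(B)
  sgn[sgn == 0] <- 1  # zero effects counted as positive
  out <- data.frame(probe_id = common, coef = b, se = se, z = z, p = p,
                    q = stats::p.adjust(p, "BH"),
                    p_bonferroni = stats::p.adjust(p, "bonferroni"),
                    n_studies = k,
                    same_direction = apply(sgn, 1, function(r)
                      all(r == r[1])),
                    q_cochran = qc,
                    p_cochran = stats::pchisq(qc, df = k - 1,
                                              lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  unpooled <- lapply(estimates, function(e)
    e[!e$probe_id %in% common, , drop = FALSE])
  attr(out, "unpooled") <- unpooled
  out
}

#' Cross-study direction concordance
#'
#' Fraction of probes (present in all studies) whose coefficients share
#' the same sign across every study; zero coefficients are counted as
#' positive (logged via message).
#'
#' @param estimates As in [ivw_meta()]; at least two studies.
#' @return Scalar fraction in `[0, 1]`.
#' @export
direction_concordance <- function(estimates) {
  stopifnot(length(estimates) >= 2)
  common <- Reduce(intersect, lapply(estimates, `[[`, "probe_id"))
  sgn <- sapply(estimates, function(e) sign(e$coef[match(common, e$probe_id)]))
  if (any(sgn == 0)) message("zero coefficients treated as positive")
  sgn[sgn == 0] <- 1
  mean(apply(matrix(sgn, ncol = length(estimates)), 1,
             function(r) all(r == r[1])))
}

#' Overlap enrichment between two probe/gene sets
#'
#' Reports the observed overlap together with an uncorrected 2x2
#' chi-square p-value and the hypergeometric upper-tail p-value for an
#' overlap at least as large, against a finite universe.
#'
#' @param set_a,set_b Character vectors of ids (subsets of the universe).
#' @param universe_size Size of the common universe.
#' @return List: `overlap`, `expected`, `chi_square_p`, `hypergeometric_p`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  na <- length(set_a); nb <- length(set_b)
  if (na > universe_size || nb > universe_size) {
    stop("set larger than universe")
  }
  ov <- length(intersect(set_a, set_b))
  tab <- matrix(c(ov, na - ov, nb - ov, universe_size - na - nb + ov),
                2, byrow = TRUE)
  chi_p <- chi_square_test(tab)$p_value
  hyp_p <- stats::phyper(ov - 1, na, universe_size - na, nb,
                         lower.tail = FALSE)
  list(overlap = ov, expected = na * nb / universe_size,
       chi_square_p = chi_p, hypergeometric_p = hyp_p)
}
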