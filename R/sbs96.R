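#' Canonical SBS96 channel names
#'
#' Returns the 96 single-base-substitution channels in canonical
#' lexicographic order: substitution-major (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' flank A,C,G,T, then 3' flank A,C,G,T. All channels use the
#' pyrimidine-strand convention (reference base C or T).
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }), use.names = FALSE)
}

#' The C>T channels at dipyrimidine sites
#'
#' A dipyrimidine site is a cytosine whose 5' or 3' neighbour on the same
#' strand is also a pyrimidine (C or T): the substrate of UV photoproducts.
#'
#' @return Character vector of the 12 qualifying `X[C>T]Y` channel names.
#' @export
dipyrimidine_ct_channels <- function() {
  ch <- sbs96_channels()
  ct <- ch[grepl("\\[C>T\\]", ch)]
  p5 <- substr(ct, 1, 1)
  p3 <- substr(ct, 7, 7)
  ct[p5 %in% c("C", "T") | p3 %in% c("C", "T")]
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(.complement[b])), collapse = "")
  }, character(1))
}

#' Fold mutation records onto the pyrimidine strand
#'
#' Records whose reference allele is a purine (A/G) are reverse-complemented
#' (ref, alt and trinucleotide context; both alleles for DNPs) so that the
#' reference is a pyrimidine (C/T), the SBS96 convention. Pyrimidine-strand
#' records pass through unchanged; the operation is idempotent.
#'
#' @param records Data frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `context`, `class` (`"SNV"` or `"DNP"`).
#' @return The records with all rows on the pyrimidine strand.
#' @export
fold_to_pyrimidine <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("sample", "chrom", "pos", "ref", "alt", "context", "class")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  ok_bases <- grepl("^[ACGT]+$", records$ref) & grepl("^[ACGT]+$", records$alt)
  if (!all(ok_bases)) stop("non-ACGT base in ref/alt")

  snv <- records$class == "SNV"
  if (any(snv & nchar(records$ref) != 1L)) stop("SNV ref must be a single base")
  if (any(records$ref == records$alt)) stop("ref equals alt")

  flip_snv <- snv & records$ref %in% c("A", "G")
  if (any(flip_snv)) {
    records$alt[flip_snv] <- unname(.complement[records$alt[flip_snv]])
    records$ref[flip_snv] <- unname(.complement[records$ref[flip_snv]])
    ctx <- records$context[flip_snv]
    bad_ctx <- !grepl("^[ACGT]{3}$", ctx)
    if (any(bad_ctx)) stop("context must be 3 ACGT bases")
    records$context[flip_snv] <- .revcomp(ctx)
  }
  # DNPs: fold GG>AA (and generally purine-purine refs) to the pyrimidine strand
  flip_dnp <- records$class == "DNP" &
    !grepl("[CT]", substr(records$ref, 1, 1))
  if (any(flip_dnp)) {
    records$ref[flip_dnp] <- .revcomp(records$ref[flip_dnp])
    records$alt[flip_dnp] <- .revcomp(records$alt[flip_dnp])
  }
  snv_now <- records$class == "SNV"
  mid <- substr(records$context[snv_now], 2, 2)
  if (any(mid != records$ref[snv_now])) {
    stop("context middle base does not match ref after folding")
  }
  records
}

#' Build the SBS96 spectrum of one sample
#'
#' Counts folded SNVs into the 96 substitution-by-flank channels and
#' aggregates CC>TT tandem events. CC>TT events are explicit DNP rows with
#' ref CC / alt TT plus pairs of adjacent (distance 1) C>T SNVs on the same
#' chromosome, which are merged into one event and removed from the SNV
#' channels. The total burden is the number of resulting SNV events plus
#' DNP events.
#'
#' @param records Mutation records (see [fold_to_pyrimidine()]); folded
#'   internally if needed.
#' @param sample Optional sample id to subset to.
#' @return An object of class `sbs_spectrum`: list with `counts` (named
#'   integer vector over [sbs96_channels()]), `cctt_count`, `total_burden`
#'   and `sample`.
#' @export
build_spectrum <- function(records, sample = NULL) {
  if (!is.null(sample)) records <- records[records$sample == sample, , drop = FALSE]
  sid <- if (!is.null(sample)) sample else
    if (nrow(records) > 0) records$sample[1] else NA_character_
  if (nrow(records) > 0 && length(unique(records$sample)) > 1) {
    stop("records contain multiple samples; pass `sample`")
  }
  records <- fold_to_pyrimidine(records)

  dnp <- records[records$class == "DNP", , drop = FALSE]
  snv <- records[records$class == "SNV", , drop = FALSE]
  cctt <- sum(dnp$ref == "CC" & dnp$alt == "TT")

  # merge adjacent C>T SNV pairs (greedy left-to-right, non-overlapping)
  drop <- logical(nrow(snv))
  is_ct <- snv$ref == "C" & snv$alt == "T"
  if (any(is_ct)) {
    idx <- which(is_ct)
    ord <- idx[order(snv$chrom[idx], snv$pos[idx])]
    i <- 1L
    while (i < length(ord)) {
      a <- ord[i]; b <- ord[i + 1L]
      if (snv$chrom[a] == snv$chrom[b] && snv$pos[b] - snv$pos[a] == 1L) {
        drop[c(a, b)] <- TRUE
        cctt <- cctt + 1L
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  snv <- snv[!drop, , drop = FALSE]

  channels <- sbs96_channels()
  counts <- integer(length(channels))
  names(counts) <- channels
  if (nrow(snv) > 0) {
    key <- paste0(substr(snv$context, 1, 1), "[", snv$ref, ">", snv$alt, "]",
                  substr(snv$context, 3, 3))
    bad <- !key %in% channels
    if (any(bad)) stop("unrecognized channel: ", key[which(bad)[1]])
    tab <- table(key)
    counts[names(tab)] <- as.integer(tab)
  }
  n_merged_pairs <- sum(drop) / 2L
  structure(list(counts = counts, cctt_count = cctt,
                 total_burden = sum(counts) + nrow(dnp) + n_merged_pairs,
                 sample = sid),
            class = "sbs_spectrum")
}

#' Build one spectrum per sample
#'
#' @param records Mutation records for any number of samples.
#' @return Named list of `sbs_spectrum` objects.
#' @export
build_spectra <- function(records) {
  ids <- unique(records$sample)
  out <- lapply(ids, function(s) build_spectrum(records, sample = s))
  names(out) <- ids
  out
}

#' Stack spectra into a samples x 96 matrix
#'
#' @param spectra List of `sbs_spectrum` objects (see [build_spectra()]).
#' @return Numeric matrix, samples in rows, channels in columns.
#' @export
spectra_matrix <- function(spectra) {
  m <- do.call(rbind, lapply(spectra, function(s) s$counts))
  rownames(m) <- vapply(spectra, function(s) s$sample, character(1))
  m
}

#' Classify UV mutational-signature status of a spectrum
#'
#' A sample is called UV-mutant when C>T transitions at dipyrimidine sites
#' account for more than 60% of the total mutation burden, or CC>TT tandem
#' mutations for more than 5% (strict inequalities). The call depends only
#' on fractions, so it is invariant under scaling of the spectrum.
#'
#' @param spectrum An `sbs_spectrum`.
#' @param ct_threshold,cctt_threshold Rule thresholds.
#' @return One-row data frame: `sample`, `frac_ct_dipyrimidine`, `frac_cctt`,
#'   `total_burden`, `uv_mutant`.
#' @export
classify_uv <- function(spectrum, ct_threshold = 0.60, cctt_threshold = 0.05) {
  stopifnot(inherits(spectrum, "sbs_spectrum"))
  if (spectrum$total_burden <= 0) {
    warning("zero mutation burden: UV call undefined")
    return(data.frame(sample = spectrum$sample, frac_ct_dipyrimidine = NA_real_,
                      frac_cctt = NA_real_, total_burden = 0L, uv_mutant = NA))
  }
  dip <- sum(spectrum$counts[dipyrimidine_ct_channels()])
  f_ct <- dip / spectrum$total_burden
  f_cctt <- spectrum$cctt_count / spectrum$total_burden
  data.frame(sample = spectrum$sample,
             frac_ct_dipyrimidine = f_ct,
             frac_cctt = f_cctt,
             total_burden = spectrum$total_burden,
             uv_mutant = (f_ct > ct_threshold) | (f_cctt > cctt_threshold))
}

#' Classify UV status for a list of spectra
#'
#' @param spectra List of `sbs_spectrum` objects.
#' @param ... Passed to [classify_uv()].
#' @return Data frame, one row per sample.
#' @export
classify_uv_all <- function(spectra, ...) {
  do.call(rbind, lapply(spectra, classify_uv, ...))
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction loss ||V - WH||_F by Lee-Seung
#' multiplicative updates, taking the best of `n_restarts` seeded random
#' initializations. The loss is non-increasing across iterations. On return
#' the rows of H are normalized to sum to one (signature profiles) with the
#' scale moved into W (exposures).
#'
#' @param V Non-negative matrix (e.g. samples x 96 spectra).
#' @param rank Number of signatures, `< min(dim(V))`.
#' @param seed Integer seed driving all restarts.
#' @param n_restarts Random restarts (best kept).
#' @param max_iter,tol Iteration cap and relative-loss convergence tolerance.
#' @return List with `W`, `H`, `loss`, and `loss_trace` of the best restart.
#' @export
nmf_decompose <- function(V, rank, seed = 1L, n_restarts = 10L,
                          max_iter = 2000L, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  if (all(V == 0)) stop("V is all zero")
  if (rank >= min(dim(V))) stop("rank must be < min(dim(V))")
  eps <- 1e-10
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    W <- matrix(stats::runif(nrow(V) * rank, 0.1, 1), nrow(V), rank)
    H <- matrix(stats::runif(rank * ncol(V), 0.1, 1), rank, ncol(V))
    loss_prev <- Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
      W <- W * (tcrossprod(V, H) / (W %*% tcrossprod(H) + eps))
      loss <- sqrt(sum((V - W %*% H)^2))
      trace <- c(trace, loss)
      if (is.finite(loss_prev) &&
          abs(loss_prev - loss) <= tol * max(loss_prev, eps)) break
      loss_prev <- loss
    }
    if (is.null(best) || loss < best$loss) {
      best <- list(W = W, H = H, loss = loss, loss_trace = trace)
    }
  }
  rs <- rowSums(best$H)
  rs[rs == 0] <- 1
  best$W <- best$W %*% diag(rs, nrow = length(rs))
  best$H <- diag(1 / rs, nrow = length(rs)) %*% best$H
  dimnames(best$H) <- list(paste0("S", seq_len(rank)), colnames(V))
  dimnames(best$W) <- list(rownames(V), paste0("S", seq_len(rank)))
  best
}

#' Match a signature to a reference catalogue by cosine similarity
#'
#' @param signature Numeric 96-vector (a consensus signature profile).
#' @param reference Matrix, 96 rows x k reference signatures (columns sum
#'   to 1); column names identify the signatures.
#' @param threshold Similarity above which the match flag is set (0.8).
#' @return List with `name`, `cosine`, `match` and the full `similarities`.
#' @export
cosine_match <- function(signature, reference, threshold = 0.8) {
  signature <- as.numeric(signature)
  reference <- as.matrix(reference)
  if (sqrt(sum(signature^2)) == 0) stop("zero signature vector")
  sims <- apply(reference, 2, function(ref) {
    d <- sqrt(sum(signature^2)) * sqrt(sum(ref^2))
    if (d == 0) stop("zero reference vector")
    sum(signature * ref) / d
  })
  i <- which.max(sims)
  list(name = colnames(reference)[i], cosine = unname(sims[i]),
       match = unname(sims[i]) > threshold, similarities = sims)
}

#' Shipped UV-like SBS96 profile
#'
#' A synthetic stand-in for the UV signature (COSMIC signature 7 like):
#' 0.80 of the mass spread uniformly over the 12 C>T channels at
#' dipyrimidine contexts, the remainder uniform over the other 84 channels.
#' Used by the cohort generator and as a reference profile in tests.
#'
#' @return Named numeric 96-vector summing to 1.
#' @export
uv_signature_profile <- function() {
  ch <- sbs96_channels()
  p <- rep(0.20 / 84, length(ch))
  names(p) <- ch
  dip <- dipyrimidine_ct_channels()
  p[dip] <- 0.80 / length(dip)
  p
}
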