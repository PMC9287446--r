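#' Partial least squares discriminant analysis (NIPALS)
#'
#' Two-block NIPALS partial least squares of the feature matrix against
#' one-hot class indicators, with loading deflation per component, the
#' standard PLS2 realization of PLS-DA. Features are mean-centered and
#' unit-variance scaled internally. Score vectors of successive
#' components are mutually orthogonal; weight vectors have unit norm.
#' A sample is classified to the nearest class centroid in latent space
#' (Euclidean distance).
#'
#' @param X Feature matrix, features x samples.
#' @param labels Class labels per sample (>= 2 classes).
#' @param n_components Number of latent components.
#' @param sparsity Optional number of features kept per component (see
#'   [splsda_select()]); `NULL` keeps all.
#' @return Object of class `plsda_model`: weights `W` (features x comp),
#'   loadings `P`, scores `T` (samples x comp), class centroids, selected
#'   feature ids per component, training labels and scaling parameters.
#' @export
plsda_fit <- function(X, labels, n_components = 2L, sparsity = NULL) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (ncol(X) != length(labels)) stop("labels must match samples (columns)")
  n <- ncol(X); nf <- nrow(X)
  if (!is.null(sparsity) && (sparsity <= 0 || sparsity > nf)) {
    stop("sparsity must be in 1..n_features")
  }

  ctr <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- t((X - ctr) / sdv)                      # samples x features
  Y <- stats::model.matrix(~ labels - 1)        # one-hot
  Y <- scale(Y, center = TRUE, scale = FALSE)

  W <- matrix(0, nf, n_components)
  P <- matrix(0, nf, n_components)
  Tm <- matrix(0, n, n_components)
  selected <- vector("list", n_components)
  Xd <- Xs; Yd <- Y
  for (h in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    w <- rep(0, nf)
    for (it in 1:500) {
      w_new <- crossprod(Xd, u)[, 1]
      w_new <- .sparsify(w_new, sparsity)
      w_new <- w_new / sqrt(sum(w_new^2))
      tt <- Xd %*% w_new
      q <- crossprod(Yd, tt)[, 1] / sum(tt^2)
      u_new <- Y %*% q / sum(q^2)
      if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
      w <- w_new; u <- u_new
    }
    tt <- (Xd %*% w)[, 1]
    p <- crossprod(Xd, tt)[, 1] / sum(tt^2)
    q <- crossprod(Yd, tt)[, 1] / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, p)
    Yd <- Yd - tcrossprod(tt, q)
    W[, h] <- w; P[, h] <- p; Tm[, h] <- tt
    selected[[h]] <- rownames(X)[w != 0]
  }
  rownames(W) <- rownames(P) <- rownames(X)
  rownames(Tm) <- colnames(X)

  centroids <- do.call(rbind, lapply(levels(labels), function(cl) {
    colMeans(Tm[labels == cl, , drop = FALSE])
  }))
  rownames(centroids) <- levels(labels)

  structure(list(W = W, P = P, scores = Tm, centroids = centroids,
                 selected = selected, labels = labels,
                 center = ctr, scale = sdv,
                 n_components = n_components, sparsity = sparsity),
            class = "plsda_model")
}

.sparsify <- function(w, keep) {
  if (is.null(keep) || keep >= length(w)) return(w)
  aw <- abs(w)
  # soft threshold at the (keep+1)-th largest magnitude: exactly `keep`
  # non-zero weights survive (ties broken by feature order)
  ord <- order(-aw, seq_along(w))
  lambda <- aw[ord[keep + 1L]]
  out <- sign(w) * pmax(aw - lambda, 0)
  nz <- which(out != 0)
  if (length(nz) > keep) {           # magnitude ties: keep the first `keep`
    drop <- setdiff(nz, ord[seq_len(keep)])
    out[drop] <- 0
  }
  out
}

#' Project samples and classify by nearest centroid
#'
#' @param model A `plsda_model`.
#' @param X New feature matrix (features x samples) on the training
#'   feature set; defaults to reclassifying the training scores.
#' @return Factor of predicted class labels.
#' @export
plsda_predict <- function(model, X = NULL) {
  Tm <- if (is.null(X)) model$scores else {
    Xs <- t((as.matrix(X)[rownames(model$W), , drop = FALSE] -
               model$center) / model$scale)
    R <- model$W %*% solve(crossprod(model$P, model$W))
    Xs %*% R
  }
  d <- sapply(seq_len(nrow(model$centroids)), function(i) {
    rowSums((Tm - matrix(model$centroids[i, ], nrow(Tm),
                         ncol(Tm), byrow = TRUE))^2)
  })
  d <- matrix(d, nrow = nrow(Tm))
  factor(rownames(model$centroids)[apply(d, 1, which.min)],
         levels = levels(model$labels))
}

#' Training accuracy of a PLS-DA model
#'
#' @param model A `plsda_model`.
#' @return Fraction of training samples assigned to their own class.
#' @export
plsda_accuracy <- function(model) {
  mean(plsda_predict(model) == model$labels)
}

#' Sparse PLS-DA feature selection
#'
#' PLS-DA in which each component's weight vector is soft-thresholded so
#' that exactly `keep` features carry non-zero weight (largest magnitudes
#' retained, then renormalized) — the deterministic top-k realization of
#' the LASSO constraint used to pick the most informative CpGs and
#' transcripts (keep = 25 by default). With `keep` equal to the number of
#' features it reduces to [plsda_fit()].
#'
#' @param X Feature matrix, features x samples.
#' @param labels Class labels.
#' @param keep Non-zero features per component.
#' @param n_components Number of components.
#' @return A `plsda_model` with per-component `selected` feature ids.
#' @export
splsda_select <- function(X, labels, keep = 25L, n_components = 2L) {
  plsda_fit(X, labels, n_components = n_components, sparsity = keep)
}

#' Simplified multi-block integration
#'
#' Runs sparse PLS-DA per block, concatenates the standardized selected
#' features of all blocks, and fits a plain PLS-DA on the concatenation.
#' This is a deliberately simple, deterministic substitute for full
#' multi-block covariance optimization (DIABLO-style integration): the
#' per-block feature selection is kept, the cross-block weighting is not.
#' With a single block the integration is exactly that block's sparse
#' model.
#'
#' @param blocks Named list of feature matrices (features x samples),
#'   sharing the sample axis.
#' @param labels Class labels per sample.
#' @param keep Features kept per block and component.
#' @param n_components Components for both stages.
#' @return List: `model` (the concatenation `plsda_model`), `selections`
#'   (per block, union of selected features), `block_models`.
#' @export
integrate_blocks <- function(blocks, labels, keep = 25L, n_components = 2L) {
  stopifnot(length(blocks) >= 1, !is.null(names(blocks)))
  ns <- vapply(blocks, ncol, integer(1))
  if (length(unique(ns)) != 1) stop("blocks must share the sample axis")
  block_models <- lapply(blocks, splsda_select, labels = labels,
                         keep = keep, n_components = n_components)
  selections <- lapply(block_models, function(m)
    unique(unlist(m$selected)))
  if (length(blocks) == 1L) {
    # degenerate case: integration of one block is that block's sparse model
    return(list(model = block_models[[1]], selections = selections,
                block_models = block_models))
  }
  parts <- lapply(names(blocks), function(b) {
    sub <- blocks[[b]][selections[[b]], , drop = FALSE]
    rownames(sub) <- paste(b, rownames(sub), sep = ".")
    sub
  })
  concat <- do.call(rbind, parts)
  model <- plsda_fit(concat, labels, n_components = n_components)
  list(model = model, selections = selections, block_models = block_models)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Euclidean distance with complete linkage by default, cut into
#' `n_clusters` groups. Sample order (and therefore tie-breaking) is
#' fixed by the column order of the input, so results are deterministic.
#'
#' @param m Feature matrix, features x samples (samples are clustered).
#' @param n_clusters Number of clusters to cut the tree into.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List: `clusters` (named integer assignments), `tree` (hclust).
#' @export
hier_cluster <- function(m, n_clusters, linkage = "complete") {
  if (ncol(m) < 2) {
    return(list(clusters = stats::setNames(1L, colnames(m)), tree = NULL))
  }
  if (n_clusters > ncol(m)) stop("more clusters than samples")
  tree <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                        method = linkage)
  list(clusters = stats::cutree(tree, k = n_clusters), tree = tree)
}
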