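test_that("eQTM correlation is exact against a brute-force computation", {
  set.seed(61)
  n <- 20
  beta <- matrix(runif(3 * n, 0.1, 0.9), 3, n,
                 dimnames = list(paste0("cg", 1:3), paste0("S", 1:n)))
  expr <- rbind(gA = -beta[1, ], gB = rnorm(n), gC = rnorm(n))
  colnames(expr) <- colnames(beta)
  pairs <- data.frame(cpg = paste0("cg", 1:3), gene = c("gA", "gB", "gC"))
  res <- eqtm_correlate(beta, expr, pairs)
  expect_equal(res$r[1], -1, tolerance = 1e-12)

  # brute force: covariance over sd products
  brute <- function(x, y) mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  for (i in 2:3) {
    expect_equal(res$r[i], brute(beta[i, ], expr[pairs$gene[i], ]),
                 tolerance = 1e-12)
    ref <- cor.test(beta[i, ], expr[pairs$gene[i], ])
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
  }

  # zero-variance input flags NA instead of failing
  beta0 <- beta; beta0[2, ] <- 0.5
  res0 <- eqtm_correlate(beta0, expr, pairs)
  expect_true(is.na(res0$r[2]))
})

test_that("planted eQTM couplings are detected with the expected sign", {
  co <- small_cohort()
  tr <- co$truth$eqtm
  pairs <- data.frame(cpg = tr$cpg, gene = tr$gene)
  res <- eqtm_correlate(co$beta, co$expression, pairs)
  expect_true(all(res$r < 0))          # planted slope is negative
  expect_true(mean(res$q < 0.05) >= 0.8)
})

test_that("driver scores reproduce the hand-enumerated toy cohort", {
  samples <- paste0("S", 1:8)
  uv <- setNames(c(rep(TRUE, 4), rep(FALSE, 4)), samples)
  genes <- c("gA", "gB", "gC")
  # CNV deep events per gene: 2 / 1 / 0
  cnv <- rbind(gA = c(2, -2, 0, 0, 0, 0, 0, 0),
               gB = c(0, 0, 2, 0, 0, 0, 0, 0),
               gC = rep(0, 8))
  colnames(cnv) <- samples
  # MUT counts: 4 / 2 / 0
  mut <- rbind(gA = c(1, 1, 1, 1, 0, 0, 0, 0),
               gB = c(1, 1, 0, 0, 0, 0, 0, 0),
               gC = rep(0, 8))
  colnames(mut) <- samples
  # EXP: UV deviations beyond |logFC| 2 from the non-UV mean: 1 / 1 / 0
  expr <- rbind(gA = c(9, 5, 5, 5, 5, 5, 5, 5),
                gB = c(1, 5, 5, 5, 5, 5, 5, 5),
                gC = rep(5, 8))
  colnames(expr) <- samples
  # METH: gene-mean beta deviations beyond 0.1: 3 / 0 / 0
  beta <- rbind(cg1 = c(0.8, 0.8, 0.8, 0.5, 0.5, 0.5, 0.5, 0.5),
                cg2 = c(0.9, 0.9, 0.9, 0.5, 0.5, 0.5, 0.5, 0.5),
                cg3 = rep(0.5, 8))
  colnames(beta) <- samples
  map <- data.frame(cpg = c("cg1", "cg2", "cg3"),
                    gene = c("gA", "gA", "gB"))
  ds <- driver_scores(cnv, mut, expr, beta, map, uv, genes)
  expect_equal(ds$total[ds$gene == "gA"], 4.0)
  expect_equal(ds$total[ds$gene == "gB"], 2.0)
  expect_equal(ds$total[ds$gene == "gC"], 0.0)
  expect_true(all(ds[, c("cnv_score", "mut_score", "exp_score",
                         "meth_score")] >= 0 &
                    ds[, c("cnv_score", "mut_score", "exp_score",
                           "meth_score")] <= 1))
  # each layer with events has an argmax gene scoring exactly 1
  expect_equal(max(ds$cnv_score), 1)
  expect_equal(max(ds$meth_score), 1)

  # invariance to gene and sample ordering
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  ds2 <- driver_scores(cnv[c(3, 1, 2), perm], mut[, perm], expr[, perm],
                       beta[, perm], map, uv[perm], rev(genes))
  expect_equal(ds2$total[match(ds$gene, ds2$gene)], ds$total)
  expect_error(driver_scores(cnv, mut, expr, beta, map,
                             setNames(rep(TRUE, 8), samples), genes),
               "non UV-mutant")
})

test_that("MAD filtering keeps the k most variable rows with deterministic ties", {
  expect_equal(stats::mad(1:5, constant = 1), 1)
  set.seed(62)
  m <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("r%02d", 1:50), NULL))
  m[7, ] <- 0   # constant row: MAD 0, never chosen over variable rows
  out <- mad_filter(m, k = 20)
  expect_equal(nrow(out), 20)
  expect_false("r07" %in% rownames(out))
  madv <- apply(m, 1, stats::mad, constant = 1)
  expect_true(min(madv[rownames(out)]) >= max(madv[setdiff(rownames(m),
                                                           rownames(out))]))
  expect_error(mad_filter(m, k = 0), "positive")
  expect_error(mad_filter(m, k = 100), "exceeds")
})

test_that("PLS-DA separates well-separated classes and matches chance on permuted labels", {
  set.seed(63)
  n <- 60; nf <- 50
  labels <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(nf * n), nf, n,
              dimnames = list(paste0("f", 1:nf), paste0("S", 1:n)))
  X[1:10, labels == "b"] <- X[1:10, labels == "b"] + 5
  fit <- plsda_fit(X, labels)
  expect_equal(plsda_accuracy(fit), 1.0)
  # score orthogonality and unit-norm weights
  expect_lt(abs(crossprod(fit$scores[, 1], fit$scores[, 2])), 1e-8)
  expect_equal(colSums(fit$W^2), c(1, 1), tolerance = 1e-8)

  # permuted labels carry no generalizable signal: held-out accuracy is at
  # chance (training accuracy would overfit with 50 features on 60 samples)
  hold <- seq(1, n, by = 3)
  perm_acc <- vapply(1:30, function(i) {
    pl <- sample(labels)
    fit_p <- plsda_fit(X[, -hold], pl[-hold])
    mean(plsda_predict(fit_p, X[, hold]) == pl[hold])
  }, numeric(1))
  expect_lt(abs(mean(perm_acc) - 0.5), 0.12)
  expect_error(plsda_fit(X, rep("a", n)), "2 classes")
})

test_that("prediction of held-out samples works through the rotation", {
  set.seed(64)
  n <- 40; nf <- 30
  labels <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(nf * n), nf, n,
              dimnames = list(paste0("f", 1:nf), paste0("S", 1:n)))
  X[1:5, labels == "b"] <- X[1:5, labels == "b"] + 4
  Xnew <- matrix(rnorm(nf * 10), nf, 10,
                 dimnames = list(rownames(X), paste0("T", 1:10)))
  Xnew[1:5, 6:10] <- Xnew[1:5, 6:10] + 4
  fit <- plsda_fit(X, labels)
  pred <- plsda_predict(fit, Xnew)
  expect_equal(as.character(pred), rep(c("a", "b"), each = 5))
})

test_that("sparse PLS-DA keeps exactly `keep` features and recovers planted signal carriers", {
  set.seed(65)
  n <- 60; nf <- 200
  labels <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(nf * n), nf, n,
              dimnames = list(paste0("f", 1:nf), paste0("S", 1:n)))
  carriers <- paste0("f", 1:5)
  X[carriers, labels == "b"] <- X[carriers, labels == "b"] + 3
  fit <- splsda_select(X, labels, keep = 25)
  expect_equal(lengths(fit$selected), c(25, 25))
  expect_true(all(colSums(fit$W != 0) == 25))
  expect_true(all(carriers %in% fit$selected[[1]]))

  # keep = n features reduces to the dense fit
  dense <- plsda_fit(X, labels)
  full <- splsda_select(X, labels, keep = nf)
  expect_equal(full$W, dense$W, tolerance = 1e-10)
  expect_error(splsda_select(X, labels, keep = 0), "sparsity")
})

test_that("sparse selection repeatedly recovers planted carriers across seeds", {
  hits <- vapply(1:15, function(s) {
    set.seed(600 + s)
    n <- 40; nf <- 150
    labels <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(nf * n), nf, n,
                dimnames = list(paste0("f", 1:nf), paste0("S", 1:n)))
    carriers <- paste0("f", 1:5)
    X[carriers, labels == "b"] <- X[carriers, labels == "b"] + 3
    fit <- splsda_select(X, labels, keep = 25, n_components = 2)
    all(carriers %in% unique(unlist(fit$selected)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("dense PLS-DA agrees with the mixOmics reference on training accuracy", {
  skip_if_not_installed("mixOmics")
  set.seed(66)
  n <- 40; nf <- 60
  labels <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(nf * n), nf, n,
              dimnames = list(paste0("f", 1:nf), paste0("S", 1:n)))
  X[1:8, labels == "b"] <- X[1:8, labels == "b"] + 2
  ours <- plsda_fit(X, labels)
  ref <- mixOmics::plsda(t(X), factor(labels), ncomp = 2)
  ref_pred <- predict(ref, t(X))$class$max.dist[, 2]
  expect_equal(plsda_accuracy(ours), mean(ref_pred == labels),
               tolerance = 0.06)
  # latent scores span the same separation: correlation of component 1
  expect_gt(abs(cor(ours$scores[, 1], ref$variates$X[, 1])), 0.95)
})

test_that("block integration degenerates to per-block selection and favors the informative block", {
  set.seed(67)
  n <- 50
  labels <- rep(c("a", "b"), each = n / 2)
  meth <- matrix(rnorm(120 * n), 120, n,
                 dimnames = list(paste0("cg", 1:120), paste0("S", 1:n)))
  meth[1:10, labels == "b"] <- meth[1:10, labels == "b"] + 3
  expr <- matrix(rnorm(80 * n), 80, n,
                 dimnames = list(paste0("g", 1:80), paste0("S", 1:n)))

  one <- integrate_blocks(list(meth = meth), labels, keep = 20)
  solo <- splsda_select(meth, labels, keep = 20)
  expect_equal(one$model$scores, solo$scores, tolerance = 1e-10)
  expect_equal(one$model$W, solo$W, tolerance = 1e-10)

  both <- integrate_blocks(list(meth = meth, expr = expr), labels,
                           keep = 20)
  acc_int <- plsda_accuracy(both$model)
  acc_expr <- plsda_accuracy(splsda_select(expr, labels, keep = 20))
  expect_gte(acc_int, acc_expr)
  expect_true(all(lengths(both$selections) <= 2 * 20))
  expect_error(integrate_blocks(list(a = meth, b = expr[, 1:10]), labels),
               "sample axis")
})

test_that("hierarchical clustering splits separated blobs and merges duplicates first", {
  set.seed(68)
  blob <- cbind(matrix(rnorm(20 * 10), 20, 10),
                matrix(rnorm(20 * 10, mean = 10), 20, 10))
  colnames(blob) <- paste0("S", 1:20)
  hc <- hier_cluster(blob, 2)
  expect_equal(length(unique(hc$clusters[1:10])), 1)
  expect_equal(length(unique(hc$clusters[11:20])), 1)
  expect_false(hc$clusters[1] == hc$clusters[11])

  dup <- blob
  dup[, 2] <- dup[, 1]
  hc2 <- hier_cluster(dup, 2)
  expect_equal(hc2$tree$height[1], 0)

  single <- hier_cluster(blob[, 1, drop = FALSE], 1)
  expect_equal(unname(single$clusters), 1L)
  expect_error(hier_cluster(blob, 21), "more clusters")
})
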