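test_that("total-count normalization matches the TP10K formula", {
  m <- matrix(c(1, 1, 2,
                0, 5, 5,
                0, 0, 0), nrow = 3, byrow = FALSE)  # genes x cells
  # cell 1 has counts (1,0,0); give cells distinct totals
  m <- matrix(c(1, 1, 2, 2, 3, 5, 0, 0, 0), nrow = 3)
  sce <- makeSCE(m)
  expect_warning(sce <- normalizeTotal(sce, s = 10000), "zero counts")
  expect_equal(ncol(sce), 2L)
  norm <- as.matrix(SummarizedExperiment::assay(sce, "normcounts"))
  expect_equal(unname(Matrix::colSums(norm)), rep(10000, 2))
  expect_equal(unname(norm[, 1]), c(1, 1, 2) / 4 * 10000)

  # a cell whose total already equals s is unchanged
  sce2 <- makeSCE(matrix(c(2500, 2500, 5000, 1, 0, 0), nrow = 3))
  sce2 <- normalizeTotal(sce2, s = 10000)
  expect_equal(unname(as.matrix(SummarizedExperiment::assay(sce2, "normcounts"))[, 1]),
               c(2500, 2500, 5000))
  expect_error(normalizeTotal(sce2, s = -1), "positive")
})

test_that("log transform is log1p on the normalized layer", {
  sce <- makeSCE(matrix(c(0, 1, 3, 1, 2, 0), nrow = 3))
  expect_error(logTransform(sce), "normalizeTotal")
  sce <- logTransform(normalizeTotal(sce, s = 4))
  logm <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  norm <- as.matrix(SummarizedExperiment::assay(sce, "normcounts"))
  expect_equal(logm, log1p(norm))
  expect_equal(logm[1, 1], 0)  # zero stays zero
})

test_that("HVG selection flags planted bimodal gene, never constant genes", {
  # 10 cells: gene A bimodal, gene B near-constant positive, gene C constant
  set.seed(1)
  a <- c(0, 0, 0, 0, 0, 40, 42, 38, 41, 39)
  b <- c(10, 11, 10, 9, 10, 10, 11, 9, 10, 10)
  cc <- rep(5, 10)
  sce <- makeSCE(rbind(A = a, B = b, C = cc))
  sce <- logTransform(normalizeTotal(sce, s = 50))
  sce <- setLog(sce, log1p(rbind(A = a, B = b, C = cc)))
  sce <- suppressWarnings(selectHVGs(sce, n_top = 1))
  hvg <- SummarizedExperiment::rowData(sce)$hvg
  # brute-force dispersion oracle on the log layer
  logm <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  disp <- apply(logm, 1, var) / rowMeans(logm)
  expect_equal(rownames(sce)[hvg], names(which.max(disp)))
  expect_equal(rownames(sce)[hvg], "A")

  # n_top = p flags all positive-variance genes (constant gene excluded)
  sce <- suppressWarnings(selectHVGs(sce, n_top = 3))
  hvg <- SummarizedExperiment::rowData(sce)$hvg
  expect_setequal(rownames(sce)[hvg], c("A", "B"))
})

test_that("scaling gives HVGs mean 0 and unit sample variance", {
  col <- c(1, 2, 3)
  m <- rbind(g1 = col, g2 = c(5, 1, 3), g3 = c(2, 2, 2))
  sce <- makeSCE(m)
  # bypass normalization effects: set logcounts directly
  sce <- logTransform(normalizeTotal(sce))
  sce <- setLog(sce, m)
  sce <- suppressWarnings(selectHVGs(sce, n_top = 2))
  sce <- scaleGenes(sce)
  z <- as.matrix(SummarizedExperiment::assay(sce, "scaled"))
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))  # sd([1,2,3]) = 1 with n-1
  hvg <- SummarizedExperiment::rowData(sce)$hvg
  expect_equal(unname(rowMeans(z[hvg, ])), rep(0, 2), tolerance = 1e-8)
  expect_equal(unname(apply(z[hvg, ], 1, var)), rep(1, 2), tolerance = 1e-8)
  # single-cell input: variance undefined
  expect_error(scaleGenes(makeSCE(matrix(1:3, 3, 1))), "single cell")
})

test_that("pipeline transforms are idempotent, never stacking", {
  sim <- nullFixture(seed = 3, n_cells = 50, n_genes = 30)
  once <- scaleGenes(suppressWarnings(selectHVGs(
    logTransform(normalizeTotal(sim$sce)), n_top = 20)))
  twice <- scaleGenes(suppressWarnings(selectHVGs(
    logTransform(normalizeTotal(once)), n_top = 20)))
  for (a in c("normcounts", "logcounts", "scaled"))
    expect_equal(as.matrix(SummarizedExperiment::assay(twice, a)),
                 as.matrix(SummarizedExperiment::assay(once, a)))
})

test_that("PCA reproduces the covariance eigendecomposition", {
  set.seed(7)
  m <- matrix(rpois(20 * 5, 10), nrow = 5)  # 5 genes x 20 cells
  sce <- makeSCE(m, preprocess = TRUE)
  sce <- computePCA(sce, d = 4)
  Y <- SingleCellExperiment::reducedDim(sce, "PCA")
  V <- attr(Y, "rotation")
  lambda <- attr(Y, "eigenvalues")
  # oracle: full eigendecomposition of Sigma = Z'Z/(n-1)
  hvg <- SummarizedExperiment::rowData(sce)$hvg
  z <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled"))[hvg, ])
  sigma <- crossprod(z) / (nrow(z) - 1)
  eig <- eigen(sigma, symmetric = TRUE)
  expect_equal(lambda, eig$values[seq_along(lambda)], tolerance = 1e-8)
  # score variances equal eigenvalues; loadings orthonormal
  expect_equal(unname(apply(Y, 2, var)), unname(lambda), tolerance = 1e-8)
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(diff(lambda) <= 1e-10))

  # rank-1 data: first component explains everything
  base <- rnorm(30)
  rank1 <- outer(c(1, 2, 3), base)
  sce1 <- makeSCE(rank1 + 10, preprocess = FALSE)
  sce1 <- logTransform(normalizeTotal(sce1))
  sce1 <- setLog(sce1, rank1)
  sce1 <- scaleGenes(suppressWarnings(selectHVGs(sce1, n_top = 3)))
  expect_warning(sce1 <- computePCA(sce1, d = 3), "rank")
  Y1 <- SingleCellExperiment::reducedDim(sce1, "PCA")
  ev <- attr(Y1, "eigenvalues")
  expect_gt(ev[1] / sum(ev), 0.999)
})

test_that("PCA reconstruction error decreases with d", {
  set.seed(11)
  sce <- makeSCE(matrix(rpois(50 * 20, 8), nrow = 20), preprocess = TRUE)
  hvg <- SummarizedExperiment::rowData(sce)$hvg
  z <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled"))[hvg, ])
  errs <- vapply(c(2, 5, 10, 15), function(d) {
    sce <- computePCA(sce, d = d)
    Y <- SingleCellExperiment::reducedDim(sce, "PCA")
    norm(z - Y %*% t(attr(Y, "rotation")), "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("Leiden clustering separates planted blobs and is deterministic", {
  set.seed(5)
  n <- 120
  blob <- rep(0:1, each = n / 2)
  m <- matrix(rpois(20 * n, 8), nrow = 20)
  m[1:8, blob == 1] <- m[1:8, blob == 1] + 60  # 10-sd separation
  sce <- makeSCE(m, preprocess = TRUE)
  sce <- computePCA(sce, d = 5)
  # community granularity scales with graph size: at 120 nodes the blob
  # structure is the resolution-0.5 partition (resolution 1 subdivides)
  sce <- clusterLeiden(sce, k = 10, resolution = 0.5, seed = 42)
  expect_equal(nlevels(sce$cluster), 2L)
  expect_equal(ariOracle(sce$cluster, blob), 1)
  # same seed twice: identical labels
  sce2 <- clusterLeiden(sce, k = 10, resolution = 0.5, seed = 42)
  expect_identical(sce$cluster, sce2$cluster)
  # resolution -> 0 collapses a connected graph into one community
  one <- makeSCE(matrix(rpois(20 * 60, 8), nrow = 20), preprocess = TRUE)
  one <- computePCA(one, d = 5)
  one <- clusterLeiden(one, k = 10, resolution = 1e-4, seed = 42)
  expect_equal(nlevels(one$cluster), 1L)
  expect_error(clusterLeiden(sce, k = 500, seed = 1), "smaller")
})

test_that("batch hook applies user transforms and defaults to identity", {
  sim <- nullFixture(seed = 2, n_cells = 40, n_genes = 25)
  sce <- makeSCE(as.matrix(SummarizedExperiment::assay(sim$sce)),
                 preprocess = TRUE)
  sce <- computePCA(sce, d = 5)
  Y0 <- SingleCellExperiment::reducedDim(sce, "PCA")
  expect_equal(SingleCellExperiment::reducedDim(correctBatch(sce), "PCA"),
               Y0, ignore_attr = TRUE)
  shifted <- correctBatch(sce, hook = function(Y, batch) Y + 1)
  expect_equal(SingleCellExperiment::reducedDim(shifted, "PCA"),
               Y0 + 1, ignore_attr = TRUE)
})
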