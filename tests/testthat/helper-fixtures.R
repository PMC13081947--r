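# Shared helpers: tiny in-code fixtures and oracles.

# SCE from a genes x cells matrix with optional layers precomputed.
makeSCE <- function(m, preprocess = FALSE, n_hvgs = nrow(m)) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                       "CsparseMatrix")))
  if (preprocess) {
    sce <- normalizeTotal(sce)
    sce <- logTransform(sce)
    sce <- suppressWarnings(selectHVGs(sce, n_top = n_hvgs))
    sce <- scaleGenes(sce)
  }
  sce
}

# Overwrite the log layer with an explicit matrix (testing convenience).
setLog <- function(sce, m) {
  dimnames(m) <- dimnames(sce)
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <- m
  sce
}

# Random valid adjacency matrix (symmetric, [0,1], unit diagonal).
randomAdjacency <- function(p) {
  a <- matrix(stats::runif(p * p), p, p)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# O(p^3) loop oracle for the unsigned TOM, written independently of the
# vectorized implementation.
tomLoopOracle <- function(adj) {
  p <- nrow(adj)
  tom <- diag(p)
  k <- numeric(p)
  for (i in seq_len(p)) k[i] <- sum(adj[i, -i])
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  tom
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
exactWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Exhaustive hypergeometric upper tail: draw N of M, term has MA, P(X >= k).
exactHyperP <- function(k, M, MA, N) {
  combos <- utils::combn(M, N)
  hits <- apply(combos, 2, function(idx) sum(idx <= MA))
  mean(hits >= k)
}

# Adjusted Rand index between two label vectors (contingency-table form).
ariOracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Best overlap coefficient of a gene set against the modules of a ModuleSet.
bestOverlap <- function(genes, modules) {
  best <- 0
  for (m in setdiff(unique(moduleLabels(modules)), "grey")) {
    g <- moduleGenes(modules, m)
    best <- max(best, length(intersect(genes, g)) / min(length(genes), length(g)))
  }
  best
}

# Standard small-data pipeline through metacells for network tests.
runToMetacells <- function(sim, seed, d = 30, n_hvgs = 2000, k_mc = 8,
                           max_shared = 3, group_cols = c("cluster", "condition"),
                           cluster = TRUE) {
  sce <- sim$sce
  sce <- normalizeTotal(sce)
  sce <- logTransform(sce)
  sce <- suppressWarnings(selectHVGs(sce, n_top = min(n_hvgs, nrow(sce))))
  sce <- scaleGenes(sce)
  sce <- computePCA(sce, d = min(d, ncol(sce) - 1L))
  if (cluster) sce <- clusterLeiden(sce, k = 15, seed = seed)
  mc <- suppressWarnings(constructMetacells(
    sce, group_cols = group_cols, k = k_mc, max_shared = max_shared,
    seed = seed))
  list(sce = sce, mc = mc)
}
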