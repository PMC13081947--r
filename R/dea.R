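#' One-vs-rest Wilcoxon marker detection
#'
#' For every gene and every cluster, compares expression (log layer) of the
#' cluster's cells against all remaining cells with a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie and continuity correction),
#' then adjusts p-values by Benjamini-Hochberg across genes within each
#' cluster comparison. Alongside the test, the table reports the log2 fold
#' change M = log2((mean_in + eps) / (mean_out + eps)), the mean of the two
#' group means A = (mean_in + mean_out)/2, and the detection fractions.
#'
#' @param sce object with a \code{logcounts} assay.
#' @param clusters cluster labels (defaults to \code{colData()$cluster}).
#' @param eps pseudocount for the fold change (default 1e-6).
#' @param detection_threshold expression threshold for the detection
#'   fraction (default 0; strict inequality).
#' @return data.frame keyed by (gene, cluster) with columns statistic,
#'   pvalue, qvalue, lfc, mean_in, mean_out, avg_expr, detect_frac_in,
#'   detect_frac_out.
#' @export
rankGenesOneVsRest <- function(sce, clusters = sce$cluster, eps = 1e-6,
                               detection_threshold = 0) {
  logm <- .exprMatrix(sce, "logcounts")
  clusters <- droplevels(as.factor(clusters))
  if (nlevels(clusters) < 2L) stop("at least 2 clusters are required")
  counts_per <- table(clusters)
  usable <- names(counts_per)[counts_per >= 2L]
  if (length(usable) < length(counts_per))
    warning("skipping cluster(s) with fewer than 2 cells: ",
            paste(setdiff(names(counts_per), usable), collapse = ", "))
  p <- nrow(logm)
  ranks <- t(apply(logm, 1, rank))
  tie_terms <- apply(logm, 1, .tieTerm)

  out <- lapply(usable, function(cl) {
    in_idx <- clusters == cl
    n1 <- sum(in_idx); n2 <- sum(!in_idx); n <- n1 + n2
    r1 <- rowSums(ranks[, in_idx, drop = FALSE])
    mu <- n1 * (n + 1) / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_terms / (n * (n - 1)))
    diff <- r1 - mu
    z <- ifelse(sigma2 <= 0, 0, (diff - sign(diff) * 0.5) / sqrt(pmax(sigma2, 1e-300)))
    pval <- 2 * pnorm(-abs(z))
    pval <- pmin(pval, 1)
    mean_in <- rowMeans(logm[, in_idx, drop = FALSE])
    mean_out <- rowMeans(logm[, !in_idx, drop = FALSE])
    data.frame(gene = rownames(logm), cluster = cl,
               statistic = z, pvalue = pval,
               qvalue = p.adjust(pval, "BH"),
               lfc = log2((mean_in + eps) / (mean_out + eps)),
               mean_in = mean_in, mean_out = mean_out,
               avg_expr = (mean_in + mean_out) / 2,
               detect_frac_in =
                 rowMeans(logm[, in_idx, drop = FALSE] > detection_threshold),
               detect_frac_out =
                 rowMeans(logm[, !in_idx, drop = FALSE] > detection_threshold),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detection fraction per gene and cluster
#'
#' Fraction of a cluster's cells expressing each gene above a threshold
#' (strict inequality; threshold 0 counts any detected expression).
#'
#' @param sce object with a \code{logcounts} assay.
#' @param clusters cluster labels.
#' @param threshold expression threshold (>= 0).
#' @return genes x clusters matrix of fractions in [0, 1].
#' @export
detectionFraction <- function(sce, clusters = sce$cluster, threshold = 0) {
  stopifnot(threshold >= 0)
  logm <- .exprMatrix(sce, "logcounts")
  clusters <- droplevels(as.factor(clusters))
  vapply(levels(clusters), function(cl)
    rowMeans(logm[, clusters == cl, drop = FALSE] > threshold),
    numeric(nrow(logm)))
}

#' Top differentially expressed gene sets
#'
#' Per cluster: genes sorted by ascending adjusted p-value (ties broken by
#' descending |log fold change|, then gene id), optionally restricted to
#' positive fold changes, truncated to the top n. Shorter lists are
#' returned as-is, never padded.
#'
#' @param dea table from \code{rankGenesOneVsRest()}.
#' @param n set size cap (default 100).
#' @param require_positive_lfc keep only upregulated genes (default TRUE).
#' @return named list, cluster -> ordered gene vector.
#' @export
topDEGSets <- function(dea, n = 100, require_positive_lfc = TRUE) {
  if (!is.numeric(n) || n <= 0) stop("parameter error: n must be positive")
  sets <- lapply(split(dea, dea$cluster), function(d) {
    if (require_positive_lfc) d <- d[d$lfc > 0, , drop = FALSE]
    d <- d[order(d$qvalue, -abs(d$lfc), d$gene), , drop = FALSE]
    utils::head(d$gene, n)
  })
  sets[order(names(sets))]
}

#' Jaccard similarity matrix between gene-set collections
#'
#' J(a, b) = |A intersect B| / |A union B|; two empty sets give 0 by
#' convention (a message is emitted).
#'
#' @param sets_a,sets_b named lists of gene vectors (or \code{GeneSets});
#'   \code{sets_b} defaults to \code{sets_a} for a symmetric matrix.
#' @return matrix of Jaccard indices in [0, 1].
#' @export
jaccardMatrix <- function(sets_a, sets_b = sets_a) {
  if (is(sets_a, "GeneSets")) sets_a <- geneSetList(sets_a)
  if (is(sets_b, "GeneSets")) sets_b <- geneSetList(sets_b)
  J <- matrix(0, length(sets_a), length(sets_b),
              dimnames = list(names(sets_a), names(sets_b)))
  for (i in seq_along(sets_a)) for (j in seq_along(sets_b)) {
    a <- unique(sets_a[[i]]); b <- unique(sets_b[[j]])
    u <- length(union(a, b))
    if (u == 0) {
      message("both sets empty for pair (", names(sets_a)[i], ", ",
              names(sets_b)[j], "); Jaccard set to 0")
      J[i, j] <- 0
    } else J[i, j] <- length(intersect(a, b)) / u
  }
  J
}

# Tau on a vector of non-negative cluster means.
.tau <- function(x) {
  xmax <- max(x)
  if (xmax == 0) return(NA_real_)
  sum(1 - x / xmax) / (length(x) - 1)
}

#' Tau expression-specificity scores
#'
#' tau = sum_i (1 - x_i / x_max) / (n - 1) over the n cluster means x_i of
#' each feature: 0 for uniform expression, 1 for expression confined to a
#' single cluster. Signed features (eigengenes) must be shifted to
#' non-negative first (\code{shift = TRUE} subtracts the per-feature
#' minimum when it is negative); the formula presumes x_i >= 0.
#'
#' @param x features x cells expression matrix (or an object with a log
#'   layer), or an \linkS4class{EigengeneMatrix}.
#' @param clusters cluster labels over cells.
#' @param shift shift each feature to non-negative before the formula
#'   (default FALSE; forced TRUE for eigengene input).
#' @return named numeric vector of tau scores (NA where x_max = 0).
#' @export
tauScores <- function(x, clusters, shift = FALSE) {
  if (is(x, "EigengeneMatrix")) {
    x <- t(eigengeneValues(x))
    shift <- TRUE
  } else {
    x <- .exprMatrix(x, "logcounts")
  }
  clusters <- droplevels(as.factor(clusters))
  if (nlevels(clusters) < 2L)
    stop("parameter error: tau requires at least 2 clusters")
  means <- vapply(levels(clusters), function(cl)
    rowMeans(x[, clusters == cl, drop = FALSE]), numeric(nrow(x)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(x), NULL))
  tauFromClusterMeans(means, shift = shift)
}

#' Tau from a precomputed feature x cluster mean matrix
#'
#' @param means features x clusters matrix of mean expression.
#' @param shift subtract the per-feature minimum when negative.
#' @export
tauFromClusterMeans <- function(means, shift = FALSE) {
  means <- rbind(means)
  if (ncol(means) < 2L)
    stop("parameter error: tau requires at least 2 clusters")
  if (shift) {
    mins <- apply(means, 1, min)
    means <- means - pmin(mins, 0)
  } else if (any(means < 0)) {
    stop("negative cluster means; use shift = TRUE for signed features")
  }
  apply(means, 1, .tau)
}

#' Pairwise correlation of marker genes
#'
#' Pearson correlation of log-layer profiles across cells for a gene list;
#' a coherence check that top markers of a cluster are actually
#' co-expressed. Zero-variance genes correlate as 0 (with a warning).
#'
#' @param sce object with a \code{logcounts} assay.
#' @param genes gene ids (>= 2).
#' @export
degCoherence <- function(sce, genes) {
  stopifnot(length(genes) >= 2L)
  logm <- .exprMatrix(sce, "logcounts")
  if (ncol(logm) < 3L) stop("at least 3 cells are required")
  m <- t(logm[genes, , drop = FALSE])
  v <- .colVars(m)
  r <- suppressWarnings(cor(m))
  if (any(v == 0)) {
    warning("zero-variance gene(s): correlations reported as 0")
    r[v == 0, ] <- 0
    r[, v == 0] <- 0
  }
  diag(r) <- 1
  r
}

#' Random Forest label-transfer validation
#'
#' Trains a seeded Random Forest (500 trees) on the training data's log
#' layer restricted to the union of the DEG sets and predicts the test
#' cells, quantifying whether cluster markers generalize to an independent
#' dataset. Genes missing from either dataset are imputed as zero with a
#' warning.
#'
#' @param train,test objects with \code{logcounts} assays.
#' @param train_labels,test_labels class labels per cell.
#' @param genes DEG sets (named list) or a gene vector.
#' @param seed RNG seed.
#' @param ntree number of trees (default 500).
#' @return list with \code{confusion} (row-normalized, rows = true class),
#'   \code{class_accuracy} and \code{accuracy}.
#' @export
classifierValidation <- function(train, train_labels, test, test_labels,
                                 genes, seed, ntree = 500) {
  if (missing(seed)) stop("parameter error: seed is required")
  if (is.list(genes)) genes <- unique(unlist(genes))
  train_labels <- droplevels(as.factor(train_labels))
  test_labels <- factor(test_labels, levels = levels(train_labels))
  if (anyNA(test_labels))
    stop("class absent from training data: ",
         paste(setdiff(unique(as.character(test_labels)),
                       levels(train_labels)), collapse = ", "))
  getX <- function(obj) {
    logm <- .exprMatrix(obj, "logcounts")
    missing <- setdiff(genes, rownames(logm))
    if (length(missing))
      warning(length(missing), " gene(s) absent; imputed as 0")
    x <- matrix(0, length(genes), ncol(logm),
                dimnames = list(genes, colnames(logm)))
    present <- intersect(genes, rownames(logm))
    x[present, ] <- logm[present, ]
    t(x)
  }
  Xtr <- getX(train); Xte <- getX(test)
  colnames(Xtr) <- colnames(Xte) <- make.names(genes)
  rf <- .withSeed(seed, randomForest::randomForest(
    x = Xtr, y = train_labels, ntree = ntree))
  pred <- predict(rf, Xte)
  conf <- table(true = test_labels, predicted = pred)
  conf_norm <- sweep(conf, 1, pmax(rowSums(conf), 1), "/")
  acc <- diag(as.matrix(conf_norm))
  list(confusion = as.matrix(conf_norm),
       class_accuracy = acc,
       accuracy = mean(as.character(pred) == as.character(test_labels)))
}
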