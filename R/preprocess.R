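#' Library-size normalization
#'
#' Scales each cell's counts to a common target total s, the TP10K-style
#' transform X_norm = X / T_i * s where T_i is the cell's total UMI count.
#' Cells with zero totals are dropped with a warning. Totals are recorded in
#' \code{colData()$total_counts}. Re-running recomputes the layer from
#' counts, so the transform never stacks.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay.
#' @param s positive target total per cell (default 10,000).
#' @return the object with an added \code{normcounts} assay.
#' @export
normalizeTotal <- function(sce, s = 10000) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("parameter error: target total s must be positive")
  counts <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero counts dropped")
    sce <- sce[, totals > 0]
    counts <- SummarizedExperiment::assay(sce, "counts")
    totals <- totals[totals > 0]
  }
  norm <- counts %*% Matrix::Diagonal(x = s / totals)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "normcounts") <- norm
  sce$total_counts <- totals
  S4Vectors::metadata(sce)$target_sum <- s
  sce
}

#' Log transform
#'
#' Natural-log transform of the normalized layer, log(1 + x), so zeros map
#' to zeros and the dynamic range is compressed.
#'
#' @param sce object with a \code{normcounts} assay.
#' @return the object with an added \code{logcounts} assay.
#' @export
logTransform <- function(sce) {
  if (!"normcounts" %in% SummarizedExperiment::assayNames(sce))
    stop("state error: run normalizeTotal() before logTransform()")
  norm <- SummarizedExperiment::assay(sce, "normcounts")
  SummarizedExperiment::assay(sce, "logcounts") <- log1p(norm)
  sce
}

#' Select highly variable genes
#'
#' Ranks genes by their variance in excess of the mean-variance trend of the
#' log layer: genes are binned into 20 equal-count bins by mean expression
#' and the log dispersion ln(variance/mean) is z-scored within each bin
#' (the classic dispersion-based HVG criterion). Exactly \code{n_top} genes
#' are flagged; ties break lexicographically by gene id. Constant genes are
#' never flagged.
#'
#' @param sce object with a \code{logcounts} assay.
#' @param n_top number of genes to flag (default 2,000).
#' @param n_bins number of mean-expression bins (default 20).
#' @return the object with rowData columns \code{mean}, \code{var},
#'   \code{dispersion_z} and \code{hvg}.
#' @export
selectHVGs <- function(sce, n_top = 2000, n_bins = 20) {
  logm <- SummarizedExperiment::assay(sce, "logcounts")
  mu <- Matrix::rowMeans(logm)
  v <- .rowVars(logm)
  eligible <- v > 0 & mu > 0
  if (n_top > sum(eligible)) {
    warning("n_top exceeds the ", sum(eligible),
            " genes with positive variance; flagging all of them")
    n_top <- sum(eligible)
  }
  disp_z <- rep(NA_real_, length(mu))
  if (sum(eligible)) {
    disp <- log(v[eligible] / mu[eligible])
    bins <- cut(rank(mu[eligible], ties.method = "first"),
                breaks = min(n_bins, sum(eligible)), labels = FALSE)
    z <- disp
    for (b in unique(bins)) {
      idx <- bins == b
      s <- sd(disp[idx])
      z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
    }
    disp_z[eligible] <- z
  }
  ord <- order(-ifelse(is.na(disp_z), -Inf, disp_z), rownames(sce))
  hvg <- logical(length(mu))
  hvg[ord[seq_len(n_top)]] <- TRUE
  hvg[!eligible] <- FALSE
  SummarizedExperiment::rowData(sce)$mean <- mu
  SummarizedExperiment::rowData(sce)$var <- v
  SummarizedExperiment::rowData(sce)$dispersion_z <- disp_z
  SummarizedExperiment::rowData(sce)$hvg <- hvg
  sce
}

#' Z-score the highly variable genes
#'
#' Standardizes each flagged gene across cells on the log layer:
#' Z = (x - mean) / sd with the sample (n-1) standard deviation, giving each
#' HVG mean 0 and variance 1. The \code{scaled} assay is dense, with
#' non-HVG rows left at zero. Values can optionally be clipped at
#' \code{max_value} (default: no clipping).
#'
#' @param sce object with HVG flags from \code{selectHVGs()}.
#' @param max_value optional clip for |Z|.
#' @return the object with an added dense \code{scaled} assay.
#' @export
scaleGenes <- function(sce, max_value = Inf) {
  if (ncol(sce) < 2L) stop("variance undefined on a single cell")
  rd <- SummarizedExperiment::rowData(sce)
  if (is.null(rd$hvg)) stop("state error: run selectHVGs() first")
  logm <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  hvg <- which(rd$hvg)
  mu <- rowMeans(logm[hvg, , drop = FALSE])
  sdv <- sqrt(.rowVars(logm[hvg, , drop = FALSE]))
  stopifnot(all(sdv > 0))  # guaranteed by the HVG contract
  z <- (logm[hvg, , drop = FALSE] - mu) / sdv
  if (is.finite(max_value)) z <- pmin(pmax(z, -max_value), max_value)
  scaled <- matrix(0, nrow(sce), ncol(sce), dimnames = dimnames(logm))
  scaled[hvg, ] <- z
  SummarizedExperiment::assay(sce, "scaled") <- scaled
  sce
}

#' Principal component analysis of the scaled HVG matrix
#'
#' Computes the top-d eigenpairs of the gene-gene covariance
#' Sigma = Z'Z/(n-1) via the SVD of Z (cells x HVGs), stores cell scores
#' Y = ZV in \code{reducedDim(sce, "PCA")} and attaches the loadings,
#' eigenvalues and the explained-variance fraction as attributes. The sign
#' convention makes each loading column's largest-magnitude entry positive,
#' so results are reproducible across runs and gene orderings.
#'
#' @param sce object with a \code{scaled} assay.
#' @param d number of components (reduced to the matrix rank if larger,
#'   with a warning).
#' @return the object with a \code{"PCA"} reducedDim.
#' @export
computePCA <- function(sce, d = 30) {
  if (!"scaled" %in% SummarizedExperiment::assayNames(sce))
    stop("state error: run scaleGenes() first")
  hvg <- SummarizedExperiment::rowData(sce)$hvg
  z <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled"))[hvg, , drop = FALSE])
  n <- nrow(z)
  sv <- svd(z)
  lambda <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > sv$d[1] * max(dim(z)) * .Machine$double.eps)
  if (d > rank) {
    warning("d reduced from ", d, " to the matrix rank ", rank)
    d <- rank
  }
  V <- sv$v[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-magnitude loading entry positive
  for (k in seq_len(d)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  Y <- z %*% V
  rownames(V) <- colnames(z)
  rownames(Y) <- rownames(z)
  colnames(Y) <- colnames(V) <- paste0("PC", seq_len(d))
  attr(Y, "rotation") <- V
  attr(Y, "eigenvalues") <- lambda[seq_len(d)]
  attr(Y, "varianceExplained") <- sum(lambda[seq_len(d)]) / sum(lambda)
  SingleCellExperiment::reducedDim(sce, "PCA") <- Y
  sce
}

#' Batch-correction hook
#'
#' Applies a user-supplied transform to the PCA scores,
#' \code{hook(Y, batch) -> Y'}. The default hook is the identity; external
#' integration methods can be plugged in here without changing any
#' downstream step (all neighbour searches use the corrected matrix).
#'
#' @param sce object with a \code{"PCA"} reducedDim.
#' @param hook function of (scores, batch) returning a corrected matrix.
#' @param batch_col colData column with batch labels.
#' @export
correctBatch <- function(sce, hook = function(Y, batch) Y, batch_col = "batch") {
  Y <- SingleCellExperiment::reducedDim(sce, "PCA")
  batch <- if (batch_col %in% colnames(SummarizedExperiment::colData(sce)))
    sce[[batch_col]] else NULL
  Y2 <- hook(Y, batch)
  stopifnot(nrow(Y2) == nrow(Y))
  for (a in c("rotation", "eigenvalues", "varianceExplained"))
    attr(Y2, a) <- attr(Y, a)
  SingleCellExperiment::reducedDim(sce, "PCA") <- Y2
  sce
}

#' Leiden clustering on the PCA embedding
#'
#' Builds the exact k-nearest-neighbour graph on the PCA scores (Euclidean,
#' symmetrized by union, unit edge weights) and partitions it with the
#' Leiden algorithm under the modularity objective at the given resolution.
#' Cluster labels are relabelled by decreasing size starting at 0 and stored
#' in \code{colData()$cluster}.
#'
#' @param sce object with a \code{"PCA"} reducedDim.
#' @param k neighbours per cell (default 15); must be < number of cells.
#' @param resolution Leiden resolution (default 1.0).
#' @param seed RNG seed (mandatory: Leiden refinement is stochastic).
#' @export
clusterLeiden <- function(sce, k = 15, resolution = 1.0, seed) {
  if (missing(seed)) stop("parameter error: seed is required")
  Y <- SingleCellExperiment::reducedDim(sce, "PCA")
  n <- nrow(Y)
  if (k >= n) stop("parameter error: k must be smaller than the number of cells")
  dmat <- as.matrix(dist(Y))
  diag(dmat) <- Inf
  nn <- t(apply(dmat, 1, function(row) order(row)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comm <- .withSeed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 5))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  sce$cluster <- factor(relabel[as.character(memb)])
  sce
}

#' One-call preprocessing pipeline
#'
#' Runs normalization, log transform, HVG selection, scaling, PCA and
#' Leiden clustering with the standard defaults.
#'
#' @param sce raw counts SingleCellExperiment.
#' @param s,n_hvgs,d,k,resolution,seed see the individual steps.
#' @export
preprocess <- function(sce, s = 10000, n_hvgs = 2000, d = 30, k = 15,
                       resolution = 1.0, seed = 0) {
  sce <- normalizeTotal(sce, s)
  sce <- logTransform(sce)
  sce <- selectHVGs(sce, n_top = min(n_hvgs, nrow(sce)))
  sce <- scaleGenes(sce)
  sce <- computePCA(sce, d = min(d, ncol(sce) - 1L))
  clusterLeiden(sce, k = k, resolution = resolution, seed = seed)
}
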