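#' Module eigengenes
#'
#' For each non-grey module, standardizes the module genes across samples,
#' takes the first principal component of the resulting submatrix, rescales
#' it to unit variance and orients it so it correlates positively with the
#' module's mean standardized expression. The fraction of module variance
#' carried by PC1 is recorded per module.
#'
#' @param x expression source: SingleCellExperiment (log layer),
#'   \linkS4class{MetacellExperiment}, or genes x samples matrix.
#' @param modules a \linkS4class{ModuleSet}.
#' @param space recorded provenance, "cells" or "metacells".
#' @return an \linkS4class{EigengeneMatrix} (samples x modules).
#' @export
computeEigengenes <- function(x, modules, space = c("cells", "metacells")) {
  space <- match.arg(space)
  expr <- .exprMatrix(x, "logcounts")
  labels <- moduleLabels(modules)
  mods <- setdiff(unique(labels), "grey")
  mods <- names(sort(table(factor(labels[labels != "grey"], levels = mods)),
                     decreasing = TRUE))
  if (!length(mods)) stop("no non-grey modules to summarize")
  n <- ncol(expr)
  values <- matrix(NA_real_, n, length(mods),
                   dimnames = list(colnames(expr), mods))
  varexp <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(labels)[labels == m]
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
      stop("module '", m, "' has genes absent from the expression matrix")
    sub <- expr[genes, , drop = FALSE]
    v <- .rowVars(sub)
    if (sum(v > 0) < 2L)
      stop("module '", m, "' has fewer than 2 variable genes")
    if (any(v == 0)) {
      warning("module '", m, "': ", sum(v == 0),
              " constant gene(s) excluded from the eigengene")
      sub <- sub[v > 0, , drop = FALSE]
    }
    z <- t((sub - rowMeans(sub)) / sqrt(.rowVars(sub)))  # samples x genes
    sv <- svd(z, nu = 1, nv = 0)
    me <- sv$u[, 1]
    me <- me / sd(me)
    if (cor(me, rowMeans(z)) < 0) me <- -me
    values[, m] <- me
    varexp[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  methods::new("EigengeneMatrix", values = values,
               varianceExplained = varexp, space = space)
}

#' Eigengene-based connectivity (kME)
#'
#' Pearson correlation of every gene's profile with every module eigengene,
#' conventionally computed on the single-cell log layer even when modules
#' were defined on metacells. Zero-variance genes get kME 0 with a warning.
#'
#' @param x expression source (same sample set as the eigengenes).
#' @param eigengenes an \linkS4class{EigengeneMatrix}.
#' @return genes x modules matrix of correlations in [-1, 1].
#' @export
computeKME <- function(x, eigengenes) {
  expr <- .exprMatrix(x, "logcounts")
  me <- eigengeneValues(eigengenes)
  if (ncol(expr) != nrow(me))
    stop("contract error: expression and eigengenes cover different samples")
  v <- .rowVars(expr)
  kme <- suppressWarnings(cor(t(expr), me))
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s): kME reported as 0")
    kme[v == 0, ] <- 0
  }
  kme
}

#' Intramodular hub genes
#'
#' Per module, member genes ranked by decreasing own-module kME (ties by
#' gene id); the top n are the module's hub genes.
#'
#' @param kme genes x modules kME matrix.
#' @param modules a \linkS4class{ModuleSet}.
#' @param n hubs per module (default 10).
#' @return named list, module -> ordered gene vector.
#' @export
hubGenes <- function(kme, modules, n = 10) {
  stopifnot(n >= 1)
  labels <- moduleLabels(modules)
  mods <- intersect(colnames(kme), unique(labels))
  out <- lapply(mods, function(m) {
    genes <- intersect(names(labels)[labels == m], rownames(kme))
    ord <- order(-kme[genes, m], genes)
    utils::head(genes[ord], n)
  })
  setNames(out, mods)
}

#' Module-level Tau specificity
#'
#' Applies the Tau index to module eigengenes over clusters. Eigengenes are
#' signed, so each module's cluster means are shifted to non-negative
#' before the formula (flagged in the result's \code{"shifted"} attribute).
#'
#' @param eigengenes an \linkS4class{EigengeneMatrix} in cell space.
#' @param clusters cluster labels per cell.
#' @return named tau vector, one per module.
#' @export
moduleTau <- function(eigengenes, clusters) {
  tau <- tauScores(eigengenes, clusters, shift = TRUE)
  attr(tau, "shifted") <- TRUE
  tau
}

#' Inter-module correlation
#'
#' Pearson correlation between module eigengenes across all cells;
#' correlated modules indicate programs that co-activate in the same cells.
#'
#' @param eigengenes an \linkS4class{EigengeneMatrix} (>= 2 modules).
#' @export
intermoduleCorrelation <- function(eigengenes) {
  me <- eigengeneValues(eigengenes)
  if (ncol(me) < 2L) stop("at least 2 modules are required")
  r <- cor(me)
  diag(r) <- 1
  r
}

#' Differential module expression
#'
#' Treats the module eigengene as the unit of analysis: for every pair of
#' groups and every module, a two-sided Wilcoxon rank-sum test on the ME
#' values, BH-adjusted across modules within each group pair.
#'
#' @param eigengenes an \linkS4class{EigengeneMatrix}.
#' @param groups group labels per sample (clusters or conditions).
#' @return data.frame with module, group1, group2, statistic, pvalue,
#'   qvalue, mean_diff (group1 - group2).
#' @export
differentialModuleExpression <- function(eigengenes, groups) {
  me <- eigengeneValues(eigengenes)
  groups <- droplevels(as.factor(groups))
  sizes <- table(groups)
  usable <- names(sizes)[sizes >= 2L]
  if (length(usable) < length(sizes))
    warning("skipping degenerate group(s): ",
            paste(setdiff(names(sizes), usable), collapse = ", "))
  if (length(usable) < 2L) stop("at least 2 groups with >= 2 samples required")
  pairs <- utils::combn(usable, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    i1 <- groups == pr[1]; i2 <- groups == pr[2]
    rows <- lapply(colnames(me), function(m) {
      x <- me[i1, m]; y <- me[i2, m]
      pooled <- c(x, y)
      wz <- .wilcoxZ(rank(pooled), .tieTerm(pooled),
                     seq_along(pooled) <= length(x))
      data.frame(module = m, group1 = pr[1], group2 = pr[2],
                 statistic = wz["z"], pvalue = wz["p"],
                 mean_diff = mean(x) - mean(y), row.names = NULL)
    })
    d <- do.call(rbind, rows)
    d$qvalue <- p.adjust(d$pvalue, "BH")
    d
  })
  res <- do.call(rbind, out)
  res[, c("module", "group1", "group2", "statistic", "pvalue", "qvalue",
          "mean_diff")]
}

#' Per-group eigengene summary
#'
#' Mean ME, fraction of samples with positive ME, and quartiles per
#' (module, group); the numbers behind module-activity dot plots.
#'
#' @param eigengenes an \linkS4class{EigengeneMatrix}.
#' @param groups group labels per sample.
#' @export
moduleExpressionSummary <- function(eigengenes, groups) {
  me <- eigengeneValues(eigengenes)
  groups <- droplevels(as.factor(groups))
  out <- list()
  for (m in colnames(me)) for (g in levels(groups)) {
    v <- me[groups == g, m]
    out[[length(out) + 1L]] <- data.frame(
      module = m, group = g, mean_me = mean(v),
      frac_positive = mean(v > 0),
      q25 = unname(quantile(v, 0.25)), q50 = unname(median(v)),
      q75 = unname(quantile(v, 0.75)))
  }
  do.call(rbind, out)
}
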