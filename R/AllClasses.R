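#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom stats cor p.adjust pnorm phyper quantile median sd var dist
#'   hclust cutree as.dist prcomp rnbinom rnorm rlnorm runif wilcox.test
#'   predict setNames
#' @importFrom utils read.delim write.table head
NULL

#' Metacell expression container
#'
#' A \linkS4class{SummarizedExperiment} holding aggregated expression
#' profiles of small groups of transcriptionally similar cells. The single
#' assay \code{"meta"} is genes x metacells. Column metadata records the
#' (cluster x condition) stratum each metacell was drawn from, and
#' \code{metadata()} stores the per-metacell membership (cell ids), the
#' neighbourhood size \code{k} and the aggregation mode.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; membership, k and
#'   aggregation live in \code{metadata()}.
#' @export
setClass("MetacellExperiment", contains = "SummarizedExperiment")

setValidity("MetacellExperiment", function(object) {
  md <- S4Vectors::metadata(object)
  if (is.null(md$k) || is.null(md$membership) || is.null(md$aggregation))
    return("metadata must contain 'k', 'membership' and 'aggregation'")
  if (length(md$membership) != ncol(object))
    return("one membership set is required per metacell")
  sizes <- lengths(md$membership)
  if (length(sizes) && any(sizes != md$k))
    return("every metacell must aggregate exactly k cells")
  if (!md$aggregation %in% c("mean", "sum"))
    return("aggregation must be 'mean' or 'sum'")
  TRUE
})

#' Weighted gene co-expression network
#'
#' Holds the gene-gene correlation matrix r_ij, the soft power beta used to
#' form the (unsigned) adjacency a_ij = |r_ij|^beta, and the topological
#' overlap matrix TOM_ij. The dissimilarity d_ij = 1 - TOM_ij used for
#' clustering is derived on demand via \code{dissimMatrix()}.
#'
#' @slot genes character vector of network genes (row/column order).
#' @slot corr symmetric correlation matrix with unit diagonal.
#' @slot method correlation method ("pearson", "spearman" or "bicor").
#' @slot beta soft power threshold.
#' @slot powerScan data.frame from \code{scanSoftPower()} (may be empty).
#' @slot tom topological overlap matrix in [0, 1].
#' @export
setClass("CoexpressionNetwork",
         slots = c(genes = "character", corr = "matrix", method = "character",
                   beta = "numeric", powerScan = "data.frame", tom = "matrix"))

setValidity("CoexpressionNetwork", function(object) {
  p <- length(object@genes)
  if (!all(dim(object@corr) == c(p, p))) return("corr must be p x p")
  if (!all(dim(object@tom) == c(p, p))) return("tom must be p x p")
  if (length(object@beta) != 1L || object@beta <= 0)
    return("beta must be a single positive number")
  if (any(object@tom < -1e-12) || any(object@tom > 1 + 1e-12))
    return("TOM entries must lie in [0, 1]")
  if (max(abs(object@corr - t(object@corr))) > 1e-8) return("corr not symmetric")
  if (max(abs(object@tom - t(object@tom))) > 1e-8) return("tom not symmetric")
  TRUE
})

#' Module assignment
#'
#' Gene-to-module map produced by \code{cutModules()}. Module labels follow
#' the WGCNA colour convention ordered by decreasing module size; genes not
#' assigned to any module carry the label \code{"grey"}.
#'
#' @slot labels named character vector, gene -> module colour.
#' @slot dendrogram the average-linkage \code{hclust} tree (or NULL).
#' @slot params list of the cut parameters used.
#' @export
setClass("ModuleSet",
         slots = c(labels = "character", dendrogram = "ANY", params = "list"))

setValidity("ModuleSet", function(object) {
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    return("labels must be uniquely named by gene")
  TRUE
})

#' Module eigengene matrix
#'
#' Per-sample module activity scores: the first principal component of each
#' module's standardized expression submatrix, rescaled to unit variance and
#' oriented so it correlates positively with the module's mean expression.
#'
#' @slot values samples x modules numeric matrix.
#' @slot varianceExplained named fraction of module variance carried by PC1.
#' @slot space "cells" or "metacells".
#' @export
setClass("EigengeneMatrix",
         slots = c(values = "matrix", varianceExplained = "numeric",
                   space = "character"))

setValidity("EigengeneMatrix", function(object) {
  if (ncol(object@values) != length(object@varianceExplained))
    return("one varianceExplained entry per module is required")
  if (any(object@varianceExplained < -1e-12 | object@varianceExplained > 1 + 1e-12))
    return("varianceExplained must lie in [0, 1]")
  TRUE
})

#' Gene set collection
#'
#' Named gene sets (e.g. GMT files, DEG sets or module gene lists) with an
#' optional background universe.
#'
#' @slot sets named list of character vectors (deduplicated, non-empty).
#' @slot descriptions one description per set.
#' @slot background optional gene universe (character(0) when unset).
#' @export
setClass("GeneSets",
         slots = c(sets = "list", descriptions = "character",
                   background = "character"))

setValidity("GeneSets", function(object) {
  if (length(object@sets)) {
    if (is.null(names(object@sets))) return("sets must be named")
    if (any(lengths(object@sets) == 0L)) return("gene sets must be non-empty")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
      return("gene sets must not contain duplicates")
  }
  TRUE
})

#' Module preservation report
#'
#' Per-module permutation Z statistics comparing a reference module
#' definition against an independent test dataset: Z_density (does the
#' module stay densely connected), Z_connectivity (is the intramodular
#' connectivity pattern preserved), their mean Z_summary, and the median
#' preservation rank (1 = most preserved).
#'
#' @slot stats data.frame with one row per evaluated module.
#' @slot nPerm number of permutations used for the null.
#' @slot seed RNG seed of the permutation stream.
#' @export
setClass("PreservationReport",
         slots = c(stats = "data.frame", nPerm = "integer", seed = "integer"))

setValidity("PreservationReport", function(object) {
  need <- c("module", "Z_density", "Z_connectivity", "Z_summary", "median_rank")
  if (!all(need %in% colnames(object@stats)))
    return(paste("stats must contain columns:", paste(need, collapse = ", ")))
  ok <- is.finite(object@stats$Z_summary)
  exp_sum <- (object@stats$Z_density + object@stats$Z_connectivity) / 2
  if (any(abs(object@stats$Z_summary[ok] - exp_sum[ok]) > 1e-8))
    return("Z_summary must be the mean of Z_density and Z_connectivity")
  TRUE
})
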