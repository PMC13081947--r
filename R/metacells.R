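#' Aggregate similar cells into metacells
#'
#' De-sparsifies the expression matrix for network construction by
#' averaging small groups of transcriptionally similar cells. Within each
#' stratum (by default cluster x condition), seed cells are drawn without
#' replacement under a seeded RNG; each seed's metacell is the seed plus
#' its k-1 nearest neighbours in PCA space within the stratum. A candidate
#' is rejected when it shares more than \code{max_shared} cells with any
#' accepted metacell, and sampling stops at \code{target_per_stratum} or
#' exhaustion. Expression is the mean of the log layer per gene
#' (\code{aggregation = "mean"}), or the sum of raw counts for a
#' pseudobulk-style matrix (\code{"sum"}).
#'
#' @param sce preprocessed SingleCellExperiment with a \code{"PCA"}
#'   reducedDim and a \code{logcounts} assay.
#' @param group_cols colData columns defining the strata
#'   (default \code{c("cluster", "condition")}; columns missing from
#'   colData are ignored).
#' @param k cells per metacell (default 25).
#' @param max_shared maximum cell overlap between accepted metacells
#'   (default 10).
#' @param target_per_stratum metacells to attempt per stratum (default
#'   floor(stratum size / 3)).
#' @param aggregation "mean" (log layer) or "sum" (raw counts).
#' @param seed RNG seed (mandatory).
#' @return a \linkS4class{MetacellExperiment}.
#' @export
constructMetacells <- function(sce, group_cols = c("cluster", "condition"),
                               k = 25, max_shared = 10,
                               target_per_stratum = NULL,
                               aggregation = c("mean", "sum"), seed) {
  if (missing(seed)) stop("parameter error: seed is required")
  aggregation <- match.arg(aggregation)
  Y <- SingleCellExperiment::reducedDim(sce, "PCA")
  cd <- SummarizedExperiment::colData(sce)
  group_cols <- intersect(group_cols, colnames(cd))
  stratum <- if (length(group_cols))
    interaction(as.data.frame(cd[, group_cols, drop = FALSE]),
                drop = TRUE, sep = ":")
  else factor(rep("all", ncol(sce)))
  expr <- if (aggregation == "mean")
    as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  else as.matrix(SummarizedExperiment::assay(sce, "counts"))

  members <- list(); groups <- character(0)
  .withSeed(seed, {
    for (st in levels(stratum)) {
      idx <- which(stratum == st)
      if (length(idx) < k) {
        warning("stratum '", st, "' smaller than k; skipped")
        next
      }
      target <- if (is.null(target_per_stratum))
        max(1L, floor(length(idx) / 3)) else target_per_stratum
      D <- as.matrix(dist(Y[idx, , drop = FALSE]))
      diag(D) <- Inf
      seeds <- sample(seq_along(idx))
      accepted <- list()
      for (sd_i in seeds) {
        if (length(accepted) >= target) break
        nbrs <- order(D[sd_i, ])[seq_len(k - 1L)]
        cand <- idx[c(sd_i, nbrs)]
        ok <- all(vapply(accepted,
                         function(a) length(intersect(a, cand)) <= max_shared,
                         logical(1)))
        if (ok) accepted[[length(accepted) + 1L]] <- cand
      }
      if (length(accepted)) {
        members <- c(members, accepted)
        groups <- c(groups, rep(st, length(accepted)))
      }
    }
  })
  if (!length(members)) stop("no metacells could be constructed")
  agg <- vapply(members, function(cells) {
    if (aggregation == "mean") rowMeans(expr[, cells, drop = FALSE])
    else rowSums(expr[, cells, drop = FALSE])
  }, numeric(nrow(expr)))
  colnames(agg) <- sprintf("mc%04d", seq_along(members))
  names(members) <- colnames(agg)
  members <- lapply(members, function(cells) colnames(sce)[cells])
  methods::new(
    "MetacellExperiment",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(meta = agg),
      colData = S4Vectors::DataFrame(group = groups,
                                     row.names = colnames(agg)),
      metadata = list(membership = members, k = k,
                      aggregation = aggregation, seed = seed,
                      max_shared = max_shared)))
}
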