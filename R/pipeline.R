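#' Run the two analysis tracks end to end
#'
#' Executes the stages in dependency order — simulate (or read input),
#' preprocess, then the marker track (dea) and the network track
#' (metacells, network, modules) and finally the comparison — writing each
#' stage's tables and a JSON run manifest into its own subdirectory of
#' \code{out_dir}. A stage whose manifest and outputs already exist is
#' skipped, so a partially deleted output tree resumes from where it
#' stopped.
#'
#' @param config named list (or path to a JSON/YAML-free simple
#'   \code{key = value} R file is not supported; pass a list). Recognized
#'   entries: \code{input} (MTX directory or TSV path; omit to simulate),
#'   \code{seed}, \code{target_sum}, \code{n_hvgs}, \code{n_pcs},
#'   \code{knn}, \code{resolution}, \code{top_n}, \code{metacell_k},
#'   \code{max_shared}, \code{beta}, \code{min_module_size},
#'   \code{stages} (subset of the stage names to run).
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(list(
    seed = 0, target_sum = 10000, n_hvgs = 2000, n_pcs = 30, knn = 15,
    resolution = 1.0, top_n = 100, metacell_k = 25, max_shared = 10,
    beta = "auto", min_module_size = 30,
    stages = c("simulate", "preprocess", "dea", "metacells", "network",
               "modules", "compare")), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  manifest <- function(stage, params, files) {
    jsonlite::write_json(
      list(toolkit = "scmodules",
           version = as.character(utils::packageVersion("scmodules")),
           stage = stage, params = params, seed = cfg$seed,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
           outputs = files),
      file.path(out_dir, stage, "manifest.json"), auto_unbox = TRUE)
  }
  done <- function(stage) file.exists(file.path(out_dir, stage, "manifest.json"))
  stage_dir <- function(stage) {
    d <- file.path(out_dir, stage)
    dir.create(d, showWarnings = FALSE)
    d
  }

  # ---- input / simulate ----
  if (!is.null(cfg$input)) {
    sce <- if (dir.exists(cfg$input)) readMTXTriplet(cfg$input)
           else readDenseTable(cfg$input)
  } else if ("simulate" %in% cfg$stages) {
    d <- stage_dir("simulate")
    sim <- syntheticFixture(seed = cfg$seed,
                            n_cells = if (is.null(cfg$n_cells)) 3000 else cfg$n_cells,
                            n_genes = if (is.null(cfg$n_genes)) 1200 else cfg$n_genes)
    sce <- sim$sce
    if (!done("simulate")) {
      writeMTXTriplet(sce, d)
      writeTSV(data.frame(cell = colnames(sce),
                          cluster = sim$truth$cluster,
                          condition = as.character(sce$condition)),
               file.path(d, "truth_cells.tsv"))
      manifest("simulate", cfg["seed"],
               c("matrix.mtx", "features.tsv", "barcodes.tsv",
                 "truth_cells.tsv"))
    }
    res$truth <- sim$truth
  } else stop("dependency error: no input and 'simulate' not requested")

  # ---- preprocess ----
  if (!"preprocess" %in% cfg$stages) return(invisible(res))
  d <- stage_dir("preprocess")
  sce <- preprocess(sce, s = cfg$target_sum,
                    n_hvgs = min(cfg$n_hvgs, nrow(sce)),
                    d = cfg$n_pcs, k = cfg$knn,
                    resolution = cfg$resolution, seed = cfg$seed)
  if (!done("preprocess")) {
    writeTSV(data.frame(cell = colnames(sce), cluster = sce$cluster),
             file.path(d, "clusters.tsv"))
    writeTSV(SingleCellExperiment::reducedDim(sce, "PCA")[, , drop = FALSE],
             file.path(d, "pca_scores.tsv"))
    manifest("preprocess",
             cfg[c("target_sum", "n_hvgs", "n_pcs", "knn", "resolution", "seed")],
             c("clusters.tsv", "pca_scores.tsv"))
  }
  res$sce <- sce

  # ---- dea track ----
  if ("dea" %in% cfg$stages) {
    d <- stage_dir("dea")
    dea <- rankGenesOneVsRest(sce)
    degs <- topDEGSets(dea, n = cfg$top_n)
    if (!done("dea")) {
      writeTSV(dea, file.path(d, "dea_table.tsv"))
      writeGMT(degs, file.path(d, "deg_sets.gmt"))
      writeTSV(jaccardMatrix(degs), file.path(d, "deg_jaccard.tsv"))
      tau <- tauScores(sce, sce$cluster)
      writeTSV(data.frame(gene = names(tau), tau = tau),
               file.path(d, "tau.tsv"))
      manifest("dea", cfg[c("top_n", "seed")],
               c("dea_table.tsv", "deg_sets.gmt", "deg_jaccard.tsv", "tau.tsv"))
    }
    res$dea <- dea; res$degs <- degs
  }

  # ---- network track ----
  if ("metacells" %in% cfg$stages) {
    d <- stage_dir("metacells")
    mc <- constructMetacells(sce, k = cfg$metacell_k,
                             max_shared = cfg$max_shared, seed = cfg$seed)
    if (!done("metacells")) {
      writeTSV(as.matrix(SummarizedExperiment::assay(mc, "meta")),
               file.path(d, "metacells.tsv"))
      jsonlite::write_json(membership(mc),
                           file.path(d, "membership.json"))
      manifest("metacells", cfg[c("metacell_k", "max_shared", "seed")],
               c("metacells.tsv", "membership.json"))
    }
    res$metacells <- mc
  }
  if ("network" %in% cfg$stages) {
    if (is.null(res$metacells))
      stop("dependency error: stage 'network' needs 'metacells'")
    d <- stage_dir("network")
    hvg <- rownames(sce)[SummarizedExperiment::rowData(sce)$hvg]
    expr <- SummarizedExperiment::assay(res$metacells, "meta")
    keep <- intersect(hvg, rownames(expr)[.rowVars(expr) > 0])
    net <- buildNetwork(res$metacells, genes = keep, beta = cfg$beta)
    mods <- cutModules(net, expr = res$metacells,
                       min_module_size = cfg$min_module_size)
    if (!done("network")) {
      if (nrow(powerScan(net)))
        writeTSV(powerScan(net), file.path(d, "soft_power_scan.tsv"))
      writeTSV(data.frame(gene = names(moduleLabels(mods)),
                          module = moduleLabels(mods)),
               file.path(d, "module_assignment.tsv"))
      manifest("network", cfg[c("beta", "min_module_size", "seed")],
               c("module_assignment.tsv"))
    }
    res$network <- net; res$modules <- mods
  }
  if ("modules" %in% cfg$stages) {
    if (is.null(res$modules))
      stop("dependency error: stage 'modules' needs 'network'")
    d <- stage_dir("modules")
    if (length(setdiff(unique(moduleLabels(res$modules)), "grey"))) {
      eg <- computeEigengenes(sce, res$modules, space = "cells")
      kme <- computeKME(sce, eg)
      if (!done("modules")) {
        writeTSV(eigengeneValues(eg), file.path(d, "eigengenes.tsv"))
        writeTSV(kme, file.path(d, "kme.tsv"))
        tau_m <- moduleTau(eg, sce$cluster)
        writeTSV(data.frame(module = names(tau_m), tau = tau_m),
                 file.path(d, "module_tau.tsv"))
        if (ncol(eigengeneValues(eg)) >= 2)
          writeTSV(intermoduleCorrelation(eg),
                   file.path(d, "intermodule_correlation.tsv"))
        manifest("modules", cfg["seed"],
                 c("eigengenes.tsv", "kme.tsv", "module_tau.tsv"))
      }
      res$eigengenes <- eg; res$kme <- kme
    }
  }

  # ---- comparison ----
  if ("compare" %in% cfg$stages && !is.null(res$modules) &&
      !is.null(res$degs)) {
    d <- stage_dir("compare")
    if (!done("compare")) {
      writeTSV(moduleDEGJaccard(res$modules, res$degs),
               file.path(d, "module_deg_jaccard.tsv"))
      manifest("compare", cfg["seed"], "module_deg_jaccard.tsv")
    }
  }
  invisible(res)
}
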