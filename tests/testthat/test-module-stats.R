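moduleSetFor <- function(labels) {
  methods::new("ModuleSet", labels = labels, dendrogram = NULL, params = list())
}

test_that("eigengenes: rank-1 module, sign rule, decomposition oracle", {
  # identical columns: ME is that profile standardized, varexp = 1
  base <- c(1, 3, 2, 5, 4)
  m <- rbind(g1 = base, g2 = base, g3 = base)
  colnames(m) <- paste0("c", 1:5)
  ms <- moduleSetFor(setNames(rep("blue", 3), rownames(m)))
  eg <- computeEigengenes(m, ms, space = "cells")
  me <- eigengeneValues(eg)[, "blue"]
  expect_equal(unname(me), unname((base - mean(base)) / sd(base)),
               tolerance = 1e-10)
  expect_equal(unname(varianceExplained(eg)["blue"]), 1)
  expect_gte(cor(me, base), 0.99)  # sign follows mean expression

  # 3-gene, 5-cell module against an independent full SVD
  set.seed(21)
  m2 <- matrix(rnorm(15), 3, 5, dimnames = list(paste0("g", 1:3), paste0("c", 1:5)))
  ms2 <- moduleSetFor(setNames(rep("red", 3), rownames(m2)))
  eg2 <- computeEigengenes(m2, ms2, space = "cells")
  z <- scale(t(m2))
  full <- svd(z)
  u1 <- full$u[, 1] / sd(full$u[, 1])
  if (cor(u1, rowMeans(z)) < 0) u1 <- -u1
  expect_equal(unname(eigengeneValues(eg2)[, "red"]), u1, tolerance = 1e-10)
  expect_equal(unname(varianceExplained(eg2)["red"]),
               full$d[1]^2 / sum(full$d^2), tolerance = 1e-10)

  # gene-order permutation does not change the eigengene
  perm <- sample(rownames(m2))
  eg3 <- computeEigengenes(m2[perm, ], ms2, space = "cells")
  expect_equal(eigengeneValues(eg3), eigengeneValues(eg2), tolerance = 1e-10)

  expect_error(computeEigengenes(m2, moduleSetFor(c(g1 = "solo"))), "2")
})

test_that("kME is bounded correlation with planted-hub ordering", {
  sim <- syntheticFixture(seed = 9, n_cells = 800, n_genes = 600)
  sce <- logTransform(normalizeTotal(sim$sce))
  tg <- sim$truth$module_genes[[1]]       # shared-activity module, hub first
  labels <- setNames(ifelse(names(sim$truth$module_of) %in% tg, "blue", "grey"),
                     names(sim$truth$module_of))
  ms <- moduleSetFor(labels)
  eg <- computeEigengenes(sce, ms, space = "cells")
  kme <- computeKME(sce, eg)
  expect_true(all(kme >= -1 - 1e-12 & kme <= 1 + 1e-12))
  hub <- sim$truth$hub_gene[1]
  peripheral <- tg[which.min(sim$truth$loading[tg])]
  expect_gt(kme[hub, "blue"], kme[peripheral, "blue"])
  # a gene whose profile is the eigengene itself has kME 1
  logm <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  logm <- rbind(logm, me_clone = eigengeneValues(eg)[, "blue"])
  kme2 <- computeKME(logm, eg)
  expect_equal(unname(kme2["me_clone", "blue"]), 1, tolerance = 1e-10)
  # own-module kME separates from cross-module kME
  labels2 <- labels
  labels2[sim$truth$module_genes[[4]]] <- "red"
  eg2 <- computeEigengenes(sce, moduleSetFor(labels2), space = "cells")
  kme3 <- computeKME(sce, eg2)
  own <- c(kme3[moduleGenes(moduleSetFor(labels2), "blue"), "blue"],
           kme3[moduleGenes(moduleSetFor(labels2), "red"), "red"])
  cross <- c(kme3[moduleGenes(moduleSetFor(labels2), "blue"), "red"],
             kme3[moduleGenes(moduleSetFor(labels2), "red"), "blue"])
  expect_gt(median(own), median(cross))
})

test_that("hub genes are ranked by own-module kME", {
  kme <- matrix(c(.9, .5, .7, .2, .1, .3), 3, 2,
                dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  ms <- moduleSetFor(c(a = "m1", b = "m1", c = "m1"))
  expect_equal(hubGenes(kme, ms, n = 10)$m1, c("a", "c", "b"))
  expect_equal(hubGenes(kme, ms, n = 1)$m1, "a")
})

test_that("module Tau distinguishes specific from ubiquitous eigengenes", {
  me <- cbind(spec = c(3, 3, 0, 0, 0, 0), flat = rep(1, 6))
  eg <- methods::new("EigengeneMatrix", values = me,
                     varianceExplained = c(spec = .5, flat = .5),
                     space = "cells")
  cl <- factor(rep(c("a", "b", "c"), each = 2))
  tau <- moduleTau(eg, cl)
  expect_equal(unname(tau["spec"]), 1)
  expect_equal(unname(tau["flat"]), 0)
  expect_true(attr(tau, "shifted"))
  # non-negative means are left unshifted: [2,1,1,1] gives tau 0.5
  me2 <- cbind(m = c(2, 2, 1, 1, 1, 1, 1, 1))
  eg2 <- methods::new("EigengeneMatrix", values = me2,
                      varianceExplained = c(m = 1), space = "cells")
  cl2 <- factor(rep(c("a", "b", "c", "d"), each = 2))
  expect_equal(unname(moduleTau(eg2, cl2)["m"]), 0.5)
})

test_that("inter-module correlation reflects shared and independent factors", {
  # background-dominated composition so library-size normalization does not
  # couple independent modules; strong loadings so each eigengene tracks its
  # activity closely
  spec <- syntheticSpec(
    n_cells = 2000, n_genes = 2400, cluster_props = 1, condition_props = 1,
    n_markers = 0,
    modules = list(
      conserved = list(n_genes = 40, activity = "shared", mu = 0,
                       loading_range = c(0.6, 1.0)),
      latent_a = list(n_genes = 40, activity = "shared", mu = 0,
                      latent_factor = 1, latent_weight = 0.97,
                      hub_loading = 1.2, loading_range = c(0.8, 1.2)),
      latent_b = list(n_genes = 40, activity = "shared", mu = 0,
                      latent_factor = 1, latent_weight = 0.97,
                      hub_loading = 1.2, loading_range = c(0.8, 1.2))),
    module_meanlog = log(1), seed = 12)
  sim <- simulateCounts(spec)
  sce <- logTransform(normalizeTotal(sim$sce))
  truth <- sim$truth
  labels <- setNames(rep("grey", length(truth$module_of)),
                     names(truth$module_of))
  labels[truth$module_genes[[1]]] <- "conserved"
  labels[truth$module_genes[[2]]] <- "latent_a"
  labels[truth$module_genes[[3]]] <- "latent_b"
  eg <- computeEigengenes(sce, moduleSetFor(labels), space = "cells")
  r <- intermoduleCorrelation(eg)
  expect_equal(unname(diag(r)), rep(1, 3))
  # the two modules sharing a latent factor co-vary strongly
  expect_gte(abs(r["latent_a", "latent_b"]), 0.8)
  # modules on independent factors stay near zero at 2,000 cells
  expect_lt(abs(r["conserved", "latent_a"]), 0.15)
})

test_that("differential module expression finds planted condition shifts", {
  sim <- syntheticFixture(seed = 15, n_cells = 1500, n_genes = 1200)
  sce <- logTransform(normalizeTotal(sim$sce))
  truth <- sim$truth
  labels <- setNames(rep("grey", length(truth$module_of)),
                     names(truth$module_of))
  labels[truth$module_genes[[2]]] <- "cond_mod"   # +1 shift in cond3
  labels[truth$module_genes[[1]]] <- "stable"
  eg <- computeEigengenes(sce, moduleSetFor(labels), space = "cells")
  dme <- differentialModuleExpression(eg, sce$condition)
  row <- dme[dme$module == "cond_mod" & dme$group1 == "cond1" &
             dme$group2 == "cond3", ]
  expect_lt(row$qvalue, 0.05)
  expect_lt(row$mean_diff, 0)   # cond3 is the active condition
  # identical distributions: large p
  same <- dme[dme$module == "stable" & dme$group1 == "cond1" &
              dme$group2 == "cond2", ]
  expect_gt(same$pvalue, 0.05)
  summ <- moduleExpressionSummary(eg, sce$condition)
  expect_true(all(summ$frac_positive >= 0 & summ$frac_positive <= 1))
})

test_that("eigengene tracks the module average on coherent modules", {
  sim <- syntheticFixture(seed = 18, n_cells = 800, n_genes = 600)
  sce <- logTransform(normalizeTotal(sim$sce))
  truth <- sim$truth
  labels <- setNames(rep("grey", length(truth$module_of)),
                     names(truth$module_of))
  labels[truth$module_genes[[1]]] <- "m"
  eg <- computeEigengenes(sce, moduleSetFor(labels), space = "cells")
  logm <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  sub <- logm[truth$module_genes[[1]], ]
  avg <- colMeans((sub - rowMeans(sub)) / sqrt(apply(sub, 1, var)))
  expect_gte(cor(eigengeneValues(eg)[, "m"], avg), 0.9)
})
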