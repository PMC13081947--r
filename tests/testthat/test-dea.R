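test_that("Wilcoxon one-vs-rest: null case, exact-oracle agreement, LFC", {
  # identical values in and out: statistic 0, p = 1
  m <- rbind(flat = rep(3, 8), other = c(1, 2, 1, 2, 1, 2, 1, 2))
  sce <- makeSCE(m)
  sce <- logTransform(normalizeTotal(sce))
  sce <- setLog(sce, m)
  cl <- factor(rep(c("a", "b"), each = 4))
  dea <- rankGenesOneVsRest(sce, cl)
  flat <- dea[dea$gene == "flat", ]
  expect_equal(flat$statistic, c(0, 0))
  expect_equal(flat$pvalue, c(1, 1))

  # normal approximation within 0.05 of exact enumeration on small groups
  x <- c(5, 6, 7); y <- c(1, 2, 3)
  m2 <- rbind(g = c(x, y))
  sce2 <- makeSCE(rbind(m2, pad = rep(1, 6)))
  sce2 <- logTransform(normalizeTotal(sce2))
  sce2 <- setLog(sce2, rbind(g = c(x, y), pad = rep(1, 6)))
  cl2 <- factor(rep(c("in", "out"), each = 3))
  dea2 <- rankGenesOneVsRest(sce2, cl2)
  p_approx <- dea2$pvalue[dea2$gene == "g" & dea2$cluster == "in"]
  p_exact <- exactWilcoxP(x, y)
  expect_equal(p_exact, 0.1)
  expect_lt(abs(p_approx - p_exact), 0.05)

  # doubling the mean gives log2 fold change ~ 1
  lfc <- dea2$lfc[dea2$gene == "g" & dea2$cluster == "in"]
  expect_equal(lfc, log2((6 + 1e-6) / (2 + 1e-6)), tolerance = 1e-10)
})

test_that("BH adjustment is monotone and bounded within each comparison", {
  set.seed(3)
  sim <- nullFixture(seed = 3, n_cells = 80, n_genes = 60)
  sce <- logTransform(normalizeTotal(sim$sce))
  cl <- factor(rep(c("a", "b"), length.out = ncol(sce)))
  dea <- rankGenesOneVsRest(sce, cl)
  for (g in split(dea, dea$cluster)) {
    expect_true(all(g$qvalue >= g$pvalue - 1e-12))
    o <- order(g$pvalue)
    expect_true(all(diff(g$qvalue[o]) >= -1e-12))
    expect_true(all(g$pvalue >= 0 & g$pvalue <= 1))
  }
})

test_that("detection fraction obeys the strict-threshold definition", {
  m <- rbind(g1 = c(2, 0, 3, 0), g2 = rep(0, 4), g3 = c(5, 5, 5, 5))
  sce <- makeSCE(m)
  sce <- logTransform(normalizeTotal(sce))
  sce <- setLog(sce, m)
  cl <- factor(rep("all", 4))
  f <- detectionFraction(sce, cl, threshold = 0)
  expect_equal(unname(f[, "all"]), c(0.5, 0, 1))
  # threshold at the max: strict inequality gives 0
  expect_equal(unname(detectionFraction(sce, cl, threshold = 5)["g3", ]), 0)
})

test_that("top DEG sets apply ranking, sign filter and truncation", {
  dea <- data.frame(
    gene = c("a", "b", "c", "d"), cluster = "c0",
    statistic = 1, pvalue = c(.01, .01, .2, .5),
    qvalue = c(.02, .02, .3, .6),
    lfc = c(1, 2, -1, 0.5))
  sets <- topDEGSets(dea, n = 10, require_positive_lfc = TRUE)
  # tie on q broken by |lfc| descending; negative lfc dropped
  expect_equal(sets$c0, c("b", "a", "d"))
  expect_equal(topDEGSets(dea, n = 1)$c0, "b")
  all_neg <- transform(dea, lfc = -abs(lfc))
  expect_length(topDEGSets(all_neg, n = 10)$c0, 0)
  expect_error(topDEGSets(dea, n = 0), "positive")
})

test_that("Jaccard matrix: endpoints, symmetry, derived value", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"),
               C = c("x", "y"), D = c("a", "b", "c"))
  J <- jaccardMatrix(sets)
  expect_equal(J["A", "D"], 1)       # identical sets
  expect_equal(J["A", "C"], 0)       # disjoint sets
  expect_equal(J["A", "B"], 0.5)     # 2 shared / 4 union
  expect_equal(J, t(J))
  expect_equal(unname(diag(J)), rep(1, 4))
  expect_message(jaccardMatrix(list(E = character(0))), "empty")
})

test_that("Tau endpoints and the shifted-eigengene rule", {
  expect_equal(unname(tauFromClusterMeans(matrix(c(5, 0, 0, 0), 1))), 1)
  expect_equal(unname(tauFromClusterMeans(matrix(c(3, 3, 3, 3), 1))), 0)
  expect_equal(unname(tauFromClusterMeans(matrix(c(2, 1, 1, 1), 1))), 0.5)
  expect_true(is.na(tauFromClusterMeans(matrix(rep(0, 3), 1))))
  expect_error(tauFromClusterMeans(matrix(1, 1, 1)), "2 clusters")
  # negative means need the shift
  expect_error(tauFromClusterMeans(matrix(c(-1, 1), 1)), "shift")
  expect_equal(unname(tauFromClusterMeans(matrix(c(1, -1, -1, -1), 1),
                                          shift = TRUE)), 1)
  # fuzz: tau always within [0, 1] on non-negative mean vectors
  set.seed(9)
  for (i in 1:1000) {
    x <- matrix(runif(sample(2:8, 1), 0, 10), 1)
    tau <- tauFromClusterMeans(x)
    expect_true(tau >= 0 && tau <= 1)
  }
})

test_that("tauScores computes cluster means from expression", {
  m <- rbind(spec = c(4, 4, 0, 0, 0, 0), flat = rep(2, 6))
  sce <- makeSCE(m)
  sce <- logTransform(normalizeTotal(sce))
  sce <- setLog(sce, m)
  cl <- factor(rep(c("a", "b", "c"), each = 2))
  tau <- tauScores(sce, cl)
  expect_equal(unname(tau["spec"]), 1)
  expect_equal(unname(tau["flat"]), 0)
  expect_error(tauScores(sce, rep("one", 6)), "2 clusters")
})

test_that("marker coherence correlation has exact endpoints", {
  set.seed(4)
  base <- rnorm(50)
  m <- rbind(g1 = base, g2 = -base, g3 = rnorm(50), zero = rep(1, 50))
  sce <- makeSCE(abs(m) + 1)
  sce <- logTransform(normalizeTotal(sce))
  sce <- setLog(sce, m)
  r <- suppressWarnings(degCoherence(sce, c("g1", "g2", "g3", "zero")))
  expect_equal(r["g1", "g1"], 1)
  expect_equal(r["g1", "g2"], -1)
  expect_equal(unname(r["zero", "g1"]), 0)
  # independent genes at n = 1000 stay near zero
  set.seed(10)
  big <- rbind(a = rnorm(1000), b = rnorm(1000))
  sceb <- makeSCE(abs(big) + 1)
  sceb <- logTransform(normalizeTotal(sceb))
  sceb <- setLog(sceb, big)
  expect_lt(abs(degCoherence(sceb, c("a", "b"))["a", "b"]), 0.1)
})

test_that("Random Forest validation: resubstitution, chance level, determinism", {
  set.seed(6)
  n <- 60
  blob <- factor(rep(c("x", "y"), each = n / 2))
  m <- matrix(rpois(12 * n, 6), nrow = 12)
  m[1:5, blob == "y"] <- m[1:5, blob == "y"] + 30
  rownames(m) <- sprintf("g%02d", 1:12)
  sce <- makeSCE(m)
  sce <- logTransform(normalizeTotal(sce))
  genes <- list(x = c("g01", "g02"), y = c("g03", "g04", "g05"))
  res <- classifierValidation(sce, blob, sce, blob, genes, seed = 1)
  expect_equal(unname(res$class_accuracy), c(1, 1))
  res2 <- classifierValidation(sce, blob, sce, blob, genes, seed = 1)
  expect_identical(res$confusion, res2$confusion)
  # permuted labels: accuracy near chance (1/2)
  set.seed(2)
  perm <- sample(blob)
  resp <- classifierValidation(sce, perm, sce, sample(blob), genes, seed = 1)
  expect_lt(abs(resp$accuracy - 0.5), 0.1 + 0.15)  # chance +/- sampling noise
  # class absent from training errors
  expect_error(classifierValidation(sce, droplevels(blob[blob == "x"]),
                                    sce, blob, genes, seed = 1),
               "absent")
})

test_that("global-null type-I error is calibrated at 2,000 genes", {
  sim <- nullFixture(seed = 42, n_cells = 600, n_genes = 2000)
  sce <- logTransform(normalizeTotal(sim$sce))
  set.seed(1)
  cl <- factor(sample(rep(c("a", "b"), length.out = ncol(sce))))
  dea <- rankGenesOneVsRest(sce, cl)
  rate <- mean(dea$pvalue[dea$cluster == "a"] < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
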