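#' Gene-gene correlation matrix
#'
#' Pairwise correlation of gene expression across metacells (or any
#' genes x samples matrix): Pearson (default), Spearman (Pearson on ranks)
#' or midweight bicorrelation. Zero-variance genes are dropped with a
#' warning.
#'
#' @param x \linkS4class{MetacellExperiment} or genes x samples matrix.
#' @param genes optional gene subset (default: all genes).
#' @param method correlation flavour.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
geneCorrelation <- function(x, genes = NULL,
                            method = c("pearson", "spearman", "bicor")) {
  method <- match.arg(method)
  m <- .exprMatrix(x)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (ncol(m) < 3L) stop("data error: at least 3 metacells are required")
  v <- .rowVars(m)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped")
    m <- m[v > 0, , drop = FALSE]
  }
  r <- switch(method,
    pearson = cor(t(m)),
    spearman = cor(t(m), method = "spearman"),
    bicor = .bicor(m))
  diag(r) <- 1
  attr(r, "method") <- method
  r
}

# Midweight bicorrelation (median/MAD weighted); genes whose MAD is zero
# fall back to Pearson-style centring by the mean, the standard fallback.
.bicor <- function(m) {
  w <- t(apply(m, 1, function(x) {
    med <- median(x)
    madv <- median(abs(x - med))
    if (madv == 0) {
      xc <- x - mean(x)
      return(xc / sqrt(sum(xc^2)))
    }
    u <- (x - med) / (9 * madv)
    wt <- (1 - u^2)^2 * (abs(u) < 1)
    xw <- (x - med) * wt
    xw / sqrt(sum(xw^2))
  }))
  r <- w %*% t(w)
  pmin(pmax(r, -1), 1)
}

#' Soft-power threshold scan
#'
#' For each candidate power beta, forms the unsigned adjacency |r|^beta and
#' evaluates how scale-free the resulting connectivity distribution is: the
#' connectivities k_i = sum_j |r_ij|^beta (j != i) are binned into 10
#' equal-width bins and log10(frequency) is regressed on log10(mean k per
#' bin); the signed fit index is R^2 times the negative sign of the slope.
#' The chosen beta is the smallest one reaching signed R^2 >= \code{rsq_cut}
#' (default 0.8), falling back to the argmax (smaller beta on ties).
#'
#' @param corr correlation matrix.
#' @param betas candidate powers (default 1:20).
#' @param rsq_cut target fit index (default 0.8).
#' @param n_bins connectivity bins for the fit (default 10).
#' @return list with \code{scan} (data.frame: beta, fit_signed_r2,
#'   mean_connectivity, median_connectivity), \code{beta} and \code{rule}.
#' @export
scanSoftPower <- function(corr, betas = 1:20, rsq_cut = 0.8, n_bins = 10) {
  stopifnot(length(betas) >= 1)
  .checkSymmetric(corr, "correlation matrix")
  a0 <- abs(corr)
  if (max(a0[upper.tri(a0)]) == min(a0[upper.tri(a0)]))
    stop("scan error: all correlations identical")
  rows <- lapply(betas, function(b) {
    a <- a0^b
    diag(a) <- 0
    k <- rowSums(a)
    data.frame(beta = b, fit_signed_r2 = .scaleFreeFit(k, n_bins),
               mean_connectivity = mean(k),
               median_connectivity = median(k))
  })
  scan <- do.call(rbind, rows)
  hit <- which(!is.na(scan$fit_signed_r2) & scan$fit_signed_r2 >= rsq_cut)
  if (length(hit)) {
    beta <- scan$beta[hit[1]]
    rule <- sprintf("smallest beta with signed R^2 >= %.2f", rsq_cut)
  } else {
    beta <- scan$beta[which.max(scan$fit_signed_r2)]
    rule <- "argmax signed R^2 (threshold not reached)"
  }
  list(scan = scan, beta = beta, rule = rule)
}

.scaleFreeFit <- function(k, n_bins = 10) {
  if (max(k) == min(k)) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 2L) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  -sign(slope) * r2
}

#' Unsigned soft-threshold adjacency
#'
#' a_ij = |r_ij|^beta with unit diagonal.
#'
#' @param corr correlation matrix.
#' @param beta positive soft power.
#' @export
softAdjacency <- function(corr, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("parameter error: beta must be positive")
  a <- abs(corr)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM: with shared-neighbour mass L_ij = sum_{u != i,j} a_iu a_uj
#' and connectivity k_i = sum_{u != i} a_iu,
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), TOM_ii = 1. Values
#' lie in [0, 1]; high overlap means two genes share much of their network
#' neighbourhood even if their direct adjacency is modest.
#'
#' @param adj symmetric adjacency with entries in [0, 1] and unit diagonal.
#' @return the TOM (symmetric, unit diagonal).
#' @export
topologicalOverlap <- function(adj) {
  .checkSymmetric(adj, "adjacency matrix")
  if (any(adj < -1e-12) || any(adj > 1 + 1e-12))
    stop("contract error: adjacency entries must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  L <- a %*% a               # L_ij = sum_{u != i,j} a_iu a_uj (diag(a) = 0)
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2  # enforce exact symmetry against FP noise
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Build a co-expression network
#'
#' Correlation -> soft-power adjacency -> TOM in one call, with the power
#' either fixed or chosen by \code{scanSoftPower()}.
#'
#' @param x \linkS4class{MetacellExperiment} or genes x samples matrix.
#' @param genes optional gene subset.
#' @param method correlation method.
#' @param beta numeric power, or \code{"auto"} to scan 1:20.
#' @param max_genes guard against accidental full-transcriptome input
#'   (default 5,000).
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
buildNetwork <- function(x, genes = NULL, method = "pearson", beta = "auto",
                         max_genes = 5000) {
  r <- geneCorrelation(x, genes = genes, method = method)
  if (nrow(r) > max_genes)
    stop("network size ", nrow(r), " exceeds max_genes = ", max_genes,
         "; subset the genes first")
  if (identical(beta, "auto")) {
    sc <- scanSoftPower(r)
    beta <- sc$beta
    scan <- sc$scan
    scan$chosen <- scan$beta == beta
    attr(scan, "rule") <- sc$rule
  } else {
    scan <- data.frame()
  }
  tom <- topologicalOverlap(softAdjacency(r, beta))
  methods::new("CoexpressionNetwork", genes = rownames(r), corr = r,
               method = attr(r, "method"), beta = as.numeric(beta),
               powerScan = scan, tom = tom)
}

#' Detect modules by adaptive tree cut of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of d = 1 - TOM, followed by an
#' adaptive, bottom-up branch cut. Walking the merge list from the bottom
#' of the tree, a growing branch locks as a candidate module as soon as it
#' reaches \code{min_module_size} genes; genes that join a branch only
#' after it locked go to the grey pool (average linkage accretes unrelated
#' genes onto tight branches near the top of the tree). Two locked
#' branches that join close above their locking heights — relative gap
#' (join - lock) / (1 - lock) at most \code{gap_frac} — are two halves of
#' one module and are merged; a high join keeps them separate. Membership
#' is then refined by eigengene connectivity: members whose own-module kME
#' falls below \code{kme_threshold} are demoted to grey, grey genes are
#' rescued into the module maximizing their kME when that kME reaches the
#' threshold, and modules falling under the size floor dissolve. The kME
#' filter is what keeps branches of unrelated genes, which any height-based
#' cut produces on noise, out of the module set. Modules are labelled with
#' WGCNA colours by decreasing size.
#'
#' @param net \linkS4class{CoexpressionNetwork} (or dissimilarity matrix).
#' @param expr expression used for the kME refinement, genes x samples
#'   (typically the metacell matrix the network was built from). Required
#'   unless \code{kme_threshold} is \code{NA}.
#' @param min_module_size smallest allowed module (default 30).
#' @param gap_frac relative height gap above which two locked branches stay
#'   separate modules (default 0.2).
#' @param kme_threshold own-module kME below which a gene is grey
#'   (default 0.30); \code{NA} disables the refinement.
#' @return a \linkS4class{ModuleSet}.
#' @export
cutModules <- function(net, expr = NULL, min_module_size = 30,
                       gap_frac = 0.2, kme_threshold = 0.30) {
  stopifnot(min_module_size >= 2)
  d <- if (is(net, "CoexpressionNetwork")) dissimMatrix(net) else net
  genes <- rownames(d)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(d)))
  hc <- hclust(as.dist(d), method = "average")
  branch <- .lockingCut(hc, min_size = min_module_size, gap_frac = gap_frac)
  labels <- ifelse(branch == 0, "grey", paste0("cand", branch))
  names(labels) <- genes
  if (all(labels == "grey")) {
    warning("no branch reaches min_module_size; all genes grey")
    return(methods::new("ModuleSet", labels = labels, dendrogram = hc,
                        params = list(min_module_size = min_module_size,
                                      gap_frac = gap_frac,
                                      kme_threshold = kme_threshold)))
  }
  if (!is.na(kme_threshold)) {
    if (is.null(expr))
      stop("expr is required for the kME refinement (or set kme_threshold = NA)")
    expr <- .exprMatrix(expr)[genes, , drop = FALSE]
    labels <- .kmeRefine(labels, expr, kme_threshold, min_module_size)
  }
  labels <- .relabelBySize(labels)
  methods::new("ModuleSet", labels = labels, dendrogram = hc,
               params = list(min_module_size = min_module_size,
                             gap_frac = gap_frac,
                             kme_threshold = kme_threshold))
}

# Bottom-up branch locking over the hclust merge list. Returns an integer
# branch id per leaf (0 = unassigned/grey).
.lockingCut <- function(hc, min_size, gap_frac = 0.2) {
  n <- length(hc$height) + 1L
  m <- hc$merge; h <- hc$height
  node_status <- character(n - 1L)   # "open", "locked", "container"
  node_mod <- integer(n - 1L)
  node_leaves <- vector("list", n - 1L)
  lock_h <- numeric(0)
  mod_leaves <- list()
  next_id <- 0L
  childInfo <- function(x) {
    if (x < 0) list(status = "open", leaves = -x, mod = NA_integer_)
    else list(status = node_status[x], leaves = node_leaves[[x]],
              mod = node_mod[x])
  }
  for (i in seq_len(n - 1L)) {
    a <- childInfo(m[i, 1]); b <- childInfo(m[i, 2])
    st <- c(a$status, b$status)
    if (all(st == "open")) {
      lv <- c(a$leaves, b$leaves)
      if (length(lv) >= min_size) {
        next_id <- next_id + 1L
        lock_h[next_id] <- h[i]
        mod_leaves[[next_id]] <- lv
        node_status[i] <- "locked"; node_mod[i] <- next_id
        node_leaves[[i]] <- integer(0)
      } else {
        node_status[i] <- "open"; node_leaves[[i]] <- lv
      }
    } else if (all(st == "locked")) {
      ref <- max(lock_h[a$mod], lock_h[b$mod])
      gap <- (h[i] - ref) / max(1 - ref, 1e-12)
      if (gap <= gap_frac) {           # two halves of one module
        keep <- a$mod; drop <- b$mod
        mod_leaves[[keep]] <- c(mod_leaves[[keep]], mod_leaves[[drop]])
        mod_leaves[[drop]] <- integer(0)
        lock_h[keep] <- h[i]
        node_status[i] <- "locked"; node_mod[i] <- keep
      } else {
        node_status[i] <- "container"
      }
      node_leaves[[i]] <- integer(0)
    } else if (any(st == "locked")) {
      lk <- if (st[1] == "locked") a else b
      ot <- if (st[1] == "locked") b else a
      # late-arriving open leaves stay grey; containers stay containers
      node_status[i] <- if (ot$status == "container") "container" else "locked"
      if (node_status[i] == "locked") node_mod[i] <- lk$mod
      node_leaves[[i]] <- integer(0)
    } else {
      node_status[i] <- "container"    # container + open: open side grey
      node_leaves[[i]] <- integer(0)
    }
  }
  labels <- integer(n)
  ids <- which(lengths(mod_leaves) > 0)
  for (j in seq_along(ids)) labels[mod_leaves[[ids[j]]]] <- j
  labels
}

# Demote weak members, rescue strong grey genes, drop undersized modules.
.kmeRefine <- function(labels, expr, kme_threshold, min_module_size) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) return(labels)
  ms <- methods::new("ModuleSet", labels = labels, dendrogram = NULL,
                     params = list())
  eg <- computeEigengenes(expr, ms, space = "metacells")
  kme <- suppressWarnings(computeKME(expr, eg))
  own <- vapply(seq_along(labels), function(i) {
    if (labels[i] == "grey") NA_real_ else kme[names(labels)[i], labels[i]]
  }, numeric(1))
  demote <- !is.na(own) & own < kme_threshold
  labels[demote] <- "grey"
  grey_idx <- which(labels == "grey")
  if (length(grey_idx)) {
    best <- max.col(kme[grey_idx, , drop = FALSE], ties.method = "first")
    best_val <- kme[cbind(grey_idx, best)]
    rescue <- best_val >= kme_threshold
    labels[grey_idx[rescue]] <- colnames(kme)[best[rescue]]
  }
  sizes <- table(labels[labels != "grey"])
  for (m in names(sizes)[sizes < min_module_size])
    labels[labels == m] <- "grey"
  labels
}

.relabelBySize <- function(labels) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) return(labels)
  sizes <- sort(table(factor(labels[labels != "grey"], levels = mods)),
                decreasing = TRUE)
  new_names <- setNames(.moduleColor(seq_along(sizes)), names(sizes))
  out <- ifelse(labels == "grey", "grey", new_names[labels])
  names(out) <- names(labels)
  out
}
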