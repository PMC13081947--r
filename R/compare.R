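#' Local hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each query set against each annotation
#' term: with universe size M, term size M_A, query size N and overlap k,
#' P = P(X >= k) for X ~ Hypergeometric(M, M_A, N). P-values are
#' BH-adjusted across terms within each query set and results are sorted by
#' ascending q. Terms are intersected with the universe first; terms with
#' no universe genes are skipped.
#'
#' @param query \linkS4class{GeneSets} or named list (e.g. module gene
#'   lists or DEG sets).
#' @param terms \linkS4class{GeneSets} or named list of annotation sets.
#' @param universe background gene vector (must contain all query genes;
#'   typically all network genes).
#' @return data.frame: query, term, overlap k, query_size N, term_size M_A,
#'   universe M, pvalue, qvalue, overlap_genes.
#' @export
hypergeometricEnrichment <- function(query, terms, universe) {
  if (is(query, "GeneSets")) query <- geneSetList(query)
  if (is(terms, "GeneSets")) terms <- geneSetList(terms)
  universe <- unique(universe)
  extra <- setdiff(unique(unlist(query)), universe)
  if (length(extra))
    stop("universe must contain all query genes (missing: ",
         paste(utils::head(extra, 3), collapse = ", "), " ...)")
  M <- length(universe)
  terms <- lapply(terms, intersect, universe)
  keep <- lengths(terms) > 0
  terms <- terms[keep]
  out <- list()
  for (qn in names(query)) {
    qs <- intersect(unique(query[[qn]]), universe)
    N <- length(qs)
    rows <- lapply(names(terms), function(tn) {
      ts <- terms[[tn]]
      ov <- intersect(qs, ts)
      k <- length(ov)
      p <- phyper(k - 1, length(ts), M - length(ts), N, lower.tail = FALSE)
      data.frame(query = qn, term = tn, overlap = k, query_size = N,
                 term_size = length(ts), universe = M, pvalue = p,
                 overlap_genes = paste(ov, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$qvalue <- p.adjust(d$pvalue, "BH")
    out[[qn]] <- d[order(d$qvalue, d$pvalue), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("query", "term", "overlap", "query_size", "term_size", "universe",
          "pvalue", "qvalue", "overlap_genes")]
}

#' Jaccard overlap between cluster DEG sets and module gene sets
#'
#' Rows are clusters, columns are (non-grey) modules; values are
#' J = |intersection| / |union|. The bridge between the cluster-level and
#' module-level representations: high J means a cluster's markers are
#' largely one module.
#'
#' @param modules a \linkS4class{ModuleSet}.
#' @param degs named list of cluster DEG sets (from \code{topDEGSets()}).
#' @export
moduleDEGJaccard <- function(modules, degs) {
  labels <- moduleLabels(modules)
  mods <- setdiff(unique(labels), "grey")
  mod_sets <- lapply(setNames(mods, mods),
                     function(m) names(labels)[labels == m])
  jaccardMatrix(degs, mod_sets)
}

# Module gene lists per condition as one flat named list.
.flattenModuleLists <- function(modules_by_condition) {
  stopifnot(!is.null(names(modules_by_condition)))
  out <- list()
  for (cond in names(modules_by_condition)) {
    x <- modules_by_condition[[cond]]
    sets <- if (is(x, "ModuleSet")) {
      labels <- moduleLabels(x)
      mods <- setdiff(unique(labels), "grey")
      lapply(setNames(mods, mods), function(m) names(labels)[labels == m])
    } else x
    names(sets) <- paste0(cond, ":", names(sets))
    out <- c(out, sets)
  }
  out
}

#' Overlap-coefficient matrix across conditions
#'
#' Szymkiewicz-Simpson overlap O(A, B) = |A intersect B| / min(|A|, |B|)
#' between every pair of condition-specific modules (grey excluded). The
#' coefficient saturates at 1 for nested sets, making it the right score
#' for asking whether a module recurs, possibly trimmed or extended, in
#' another condition.
#'
#' @param modules_by_condition named list (condition -> ModuleSet or named
#'   list of gene vectors); >= 2 conditions.
#' @return symmetric matrix with "condition:module" labels.
#' @export
overlapCoefficientMatrix <- function(modules_by_condition) {
  if (length(modules_by_condition) < 2L)
    stop("at least 2 conditions are required")
  sets <- .flattenModuleLists(modules_by_condition)
  n <- length(sets)
  O <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- sets[[i]]; b <- sets[[j]]
    m <- min(length(a), length(b))
    O[i, j] <- if (m == 0) 0 else length(intersect(a, b)) / m
  }
  O
}

#' Consolidate condition-specific modules into core programs
#'
#' Builds a graph whose nodes are condition-specific modules, with an edge
#' wherever the cross-condition overlap coefficient reaches
#' \code{threshold}; connected components are the consolidated programs.
#' A module overlapping nothing becomes a singleton (condition-specific)
#' program. Raising the threshold can only split programs, never merge.
#'
#' @param modules_by_condition named list (condition -> ModuleSet or named
#'   list of gene vectors).
#' @param threshold overlap coefficient required for an edge, in (0, 1]
#'   (default 0.5).
#' @return list with \code{programs} (each: member modules and the union
#'   gene list), \code{edges} (data.frame) and \code{threshold}.
#' @export
consolidatePrograms <- function(modules_by_condition, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  sets <- .flattenModuleLists(modules_by_condition)
  O <- overlapCoefficientMatrix(modules_by_condition)
  cond_of <- sub(":.*$", "", names(sets))
  n <- length(sets)
  adj <- O >= threshold
  # only cross-condition overlaps define edges
  same <- outer(cond_of, cond_of, "==")
  adj[same] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max", diag = FALSE)
  comp <- igraph::components(g)$membership
  programs <- lapply(sort(unique(comp)), function(cid) {
    members <- names(sets)[comp == cid]
    list(modules = members,
         genes = sort(unique(unlist(sets[members]))))
  })
  names(programs) <- paste0("program", seq_along(programs))
  ew <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = rownames(O)[ew[, 1]], to = colnames(O)[ew[, 2]],
                      overlap = O[ew], stringsAsFactors = FALSE)
  list(programs = programs, edges = edges, threshold = threshold,
       overlap = O)
}
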