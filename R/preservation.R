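#' Permutation-based module preservation
#'
#' Tests whether modules defined on a reference dataset keep their
#' co-expression structure in an independent test dataset. For each
#' non-grey module the observed statistics are
#' \itemize{
#'   \item density: mean off-diagonal adjacency |r_test|^beta among the
#'     module's genes in the test data, and
#'   \item connectivity: correlation between the members' intramodular
#'     connectivity vectors (kIM, row sums of within-module adjacency) in
#'     reference versus test.
#' }
#' A null distribution comes from \code{n_perm} random gene sets of equal
#' size drawn (seeded) from the shared network genes; Z = (observed -
#' null mean) / null sd per statistic, and Z_summary is their mean. The
#' median rank is the median of the two per-statistic ranks of the observed
#' values across modules (rank 1 = most preserved).
#'
#' @param ref,test \linkS4class{MetacellExperiment}s or genes x samples
#'   matrices; genes are matched by name.
#' @param modules \linkS4class{ModuleSet} defined on the reference genes.
#' @param beta soft power used for the adjacency (default 6).
#' @param n_perm permutations (>= 20; default 100).
#' @param seed RNG seed (mandatory).
#' @return a \linkS4class{PreservationReport}.
#' @export
modulePreservation <- function(ref, test, modules, beta = 6, n_perm = 100,
                               seed) {
  if (missing(seed)) stop("parameter error: seed is required")
  if (n_perm < 20) stop("parameter error: n_perm must be at least 20")
  ref_m <- .exprMatrix(ref)
  test_m <- .exprMatrix(test)
  labels <- moduleLabels(modules)
  universe <- intersect(intersect(names(labels), rownames(ref_m)),
                        rownames(test_m))
  ref_adj <- softAdjacency(suppressWarnings(cor(t(ref_m[universe, ]))), beta)
  test_adj <- softAdjacency(suppressWarnings(cor(t(test_m[universe, ]))), beta)
  ref_adj[is.na(ref_adj)] <- 0
  test_adj[is.na(test_adj)] <- 0

  mods <- setdiff(unique(labels), "grey")
  modstat <- function(genes) {
    idx <- match(genes, universe)
    at <- test_adj[idx, idx]; ar <- ref_adj[idx, idx]
    q <- length(idx)
    density <- (sum(at) - q) / (q * (q - 1))
    kim_ref <- rowSums(ar) - 1
    kim_test <- rowSums(at) - 1
    conn <- suppressWarnings(cor(kim_ref, kim_test))
    c(density = density, connectivity = if (is.na(conn)) 0 else conn)
  }

  rows <- list()
  .withSeed(seed, {
    for (m in mods) {
      genes_all <- names(labels)[labels == m]
      genes <- intersect(genes_all, universe)
      if (length(genes) < length(genes_all)) {
        warning("module '", m, "': ", length(genes_all) - length(genes),
                " gene(s) missing from the test data, dropped")
        if (length(genes) < 0.8 * length(genes_all))
          warning("module '", m, "' shares < 80% of its genes with the test data")
      }
      if (length(genes) < 3L) {
        warning("module '", m, "' has fewer than 3 genes in the test data; skipped")
        next
      }
      obs <- modstat(genes)
      null <- replicate(n_perm, modstat(sample(universe, length(genes))))
      mu <- rowMeans(null)
      sdv <- apply(null, 1, sd)
      zz <- vapply(names(obs), function(s) {
        if (sdv[s] == 0) {
          warning("null sd is zero for '", s, "' of module '", m, "'")
          d <- obs[s] - mu[s]
          return(if (d == 0) 0 else sign(d) * Inf)
        }
        (obs[s] - mu[s]) / sdv[s]
      }, numeric(1))
      rows[[m]] <- data.frame(
        module = m, n_genes = length(genes),
        obs_density = obs["density"], obs_connectivity = obs["connectivity"],
        Z_density = zz["density"], Z_connectivity = zz["connectivity"],
        Z_summary = mean(zz), row.names = NULL)
    }
  })
  if (!length(rows)) stop("no module could be evaluated")
  stats <- do.call(rbind, rows)
  rank_d <- rank(-stats$obs_density, ties.method = "average")
  rank_c <- rank(-stats$obs_connectivity, ties.method = "average")
  stats$median_rank <- as.integer(round((rank_d + rank_c) / 2))
  methods::new("PreservationReport", stats = stats,
               nPerm = as.integer(n_perm), seed = as.integer(seed))
}

#' Preservation verdicts
#'
#' The conventional Z-summary interpretation: > 10 strongly preserved,
#' in (2, 10] moderately preserved, <= 2 not preserved. Boundaries are
#' inclusive on the lower category (Z = 10 is moderate, Z = 2 is none).
#'
#' @param report a \linkS4class{PreservationReport} or numeric Z values.
#' @return character vector of "strong" / "moderate" / "none".
#' @export
preservationVerdict <- function(report) {
  z <- if (is(report, "PreservationReport"))
    setNames(report@stats$Z_summary, report@stats$module) else report
  ifelse(z > 10, "strong", ifelse(z > 2, "moderate", "none"))
}
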