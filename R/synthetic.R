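#' Specify a synthetic single-cell dataset
#'
#' Builds the parameter object consumed by \code{simulateCounts()}. The
#' generative model is a negative binomial count model with planted
#' structure: per-gene log-normal baselines, per-cell log-normal library
#' factors, cluster marker blocks (additive natural-log effects), and
#' co-expression modules whose genes load log-linearly on a per-cell
#' activity score. Module activities come in four flavours:
#' \itemize{
#'   \item \code{"shared"}: activity ~ Normal(mu, 1) in every cell,
#'   \item \code{"graded"}: Normal(mu_c, 1) with a cluster-dependent mean,
#'   \item \code{"sparse"}: zero-inflated; a small fraction of cells is
#'     active with activity ~ Normal(3, 1), all others are 0,
#'   \item \code{"condition"}: Normal(mu_k, 1) with a condition-dependent
#'     mean (0 suppresses the module in that condition).
#' }
#' Two modules may share a latent factor (\code{latent_factor} id plus
#' \code{latent_weight}) to plant inter-module correlation.
#'
#' @param n_cells,n_genes dataset size.
#' @param cluster_props cluster proportions (sum to 1).
#' @param condition_props condition proportions (sum to 1).
#' @param n_markers,marker_effect per-cluster marker block size and
#'   natural-log effect size.
#' @param modules list of module descriptions; each a list with
#'   \code{n_genes}, \code{activity} (one of the flavours above),
#'   \code{mu} (scalar / per-cluster / per-condition means),
#'   \code{sparse_fraction}, \code{hub_loading}, \code{loading_range},
#'   optional \code{latent_factor}, \code{latent_weight},
#'   optional \code{condition_shift} (additive per-condition mean shift).
#' @param baseline_meanlog,baseline_sdlog log-normal gene baseline.
#' @param module_meanlog,module_sdlog baseline for module/marker genes
#'   (kept moderately expressed so programs are detectable, as real
#'   transcriptional programs are).
#' @param lib_sdlog log-normal library-size sd (default 0.3).
#' @param theta negative binomial dispersion (default 2).
#' @param seed RNG seed.
#' @return a validated list of class \code{"synthetic_spec"}.
#' @export
syntheticSpec <- function(n_cells = 1000, n_genes = 500,
                          cluster_props = c(0.5, 0.5),
                          condition_props = 1,
                          n_markers = 30, marker_effect = 2.0,
                          modules = list(),
                          baseline_meanlog = log(0.3), baseline_sdlog = 1.0,
                          module_meanlog = log(1.0), module_sdlog = 0.4,
                          lib_sdlog = 0.3, theta = 2.0, seed = 1) {
  stopifnot(abs(sum(cluster_props) - 1) < 1e-8,
            abs(sum(condition_props) - 1) < 1e-8,
            theta > 0, lib_sdlog >= 0)
  n_clusters <- length(cluster_props)
  defaults <- list(activity = "shared", mu = 0, sparse_fraction = 0.05,
                   hub_loading = 1.0, loading_range = c(0.3, 0.8),
                   latent_factor = NA, latent_weight = 0.95,
                   condition_shift = rep(0, length(condition_props)))
  modules <- lapply(modules, function(m) {
    m <- utils::modifyList(defaults, m)
    stopifnot(m$n_genes >= 2, m$hub_loading >= 0, all(m$loading_range >= 0))
    m
  })
  used <- n_clusters * n_markers + sum(vapply(modules, `[[`, 0, "n_genes"))
  if (used > n_genes)
    stop("spec error: marker blocks and modules require ", used,
         " genes but n_genes = ", n_genes)
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 cluster_props = cluster_props,
                 condition_props = condition_props,
                 n_markers = n_markers, marker_effect = marker_effect,
                 modules = modules,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 module_meanlog = module_meanlog,
                 module_sdlog = module_sdlog,
                 lib_sdlog = lib_sdlog, theta = theta, seed = seed),
            class = "synthetic_spec")
}

#' Simulate a count matrix with planted clusters and modules
#'
#' Draws counts ~ NB(mean = s_i * exp(log lambda_j + marker effect +
#' sum_m w_jm z_im), dispersion theta). All randomness comes from one
#' seeded stream; the global RNG state is untouched.
#'
#' @param spec a \code{syntheticSpec()} object.
#' @return list with \code{sce} (counts + colData cluster/condition) and
#'   \code{truth} (per-cell activities and library factors; per-gene marker
#'   and module membership with loadings).
#' @export
simulateCounts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .withSeed(spec$seed, {
    n <- spec$n_cells; p <- spec$n_genes
    n_clusters <- length(spec$cluster_props)
    n_conditions <- length(spec$condition_props)

    cluster <- sample(seq_len(n_clusters), n, TRUE, prob = spec$cluster_props)
    condition <- sample(seq_len(n_conditions), n, TRUE,
                        prob = spec$condition_props)
    libf <- rlnorm(n, 0, spec$lib_sdlog)

    # gene layout: marker blocks first, then module blocks, then background
    gene_ids <- sprintf("gene%04d", seq_len(p))
    marker_of <- rep(NA_integer_, p)
    module_of <- rep(NA_integer_, p)
    loading <- rep(0, p)
    pos <- 1L
    for (c in seq_len(n_clusters)) {
      if (spec$n_markers == 0) break
      idx <- pos:(pos + spec$n_markers - 1L)
      marker_of[idx] <- c
      pos <- pos + spec$n_markers
    }
    hub_of <- integer(length(spec$modules))
    for (m in seq_along(spec$modules)) {
      mod <- spec$modules[[m]]
      idx <- pos:(pos + mod$n_genes - 1L)
      module_of[idx] <- m
      loading[idx] <- runif(mod$n_genes, mod$loading_range[1],
                            mod$loading_range[2])
      loading[idx[1]] <- mod$hub_loading
      hub_of[m] <- idx[1]
      pos <- pos + mod$n_genes
    }

    lambda <- rlnorm(p, spec$baseline_meanlog, spec$baseline_sdlog)
    structured <- !is.na(marker_of) | !is.na(module_of)
    lambda[structured] <- rlnorm(sum(structured), spec$module_meanlog,
                                 spec$module_sdlog)

    # latent factors shared across modules
    latent_ids <- unique(stats::na.omit(
      vapply(spec$modules, function(m) m$latent_factor, NA_real_)))
    latents <- if (length(latent_ids))
      matrix(rnorm(n * length(latent_ids)), n,
             dimnames = list(NULL, as.character(latent_ids))) else NULL

    # per-cell module activities
    z <- matrix(0, n, max(1L, length(spec$modules)))
    sparse_active <- vector("list", length(spec$modules))
    for (m in seq_along(spec$modules)) {
      mod <- spec$modules[[m]]
      zm <- switch(mod$activity,
        shared = rnorm(n, mod$mu[1], 1),
        graded = rnorm(n, mod$mu[cluster], 1),
        condition = rnorm(n, mod$mu[condition], 1),
        sparse = {
          act <- runif(n) < mod$sparse_fraction
          sparse_active[[m]] <- act
          ifelse(act, rnorm(n, 3, 1), 0)
        },
        stop("unknown activity type: ", mod$activity))
      if (!is.na(mod$latent_factor)) {
        w <- mod$latent_weight
        zm <- w * latents[, as.character(mod$latent_factor)] +
          sqrt(max(0, 1 - w^2)) * zm
      }
      zm <- zm + mod$condition_shift[condition]
      z[, m] <- zm
    }

    logmean <- matrix(log(lambda), n, p, byrow = TRUE)
    for (c in seq_len(n_clusters)) {
      g <- which(marker_of == c)
      if (length(g))
        logmean[cluster == c, g] <- logmean[cluster == c, g] + spec$marker_effect
    }
    for (m in seq_along(spec$modules)) {
      g <- which(module_of == m)
      logmean[, g] <- logmean[, g] + outer(z[, m], loading[g])
    }
    mu <- libf * exp(logmean)  # recycles libf down columns: mu[i,j]
    counts <- matrix(rnbinom(n * p, size = spec$theta, mu = mu), n, p)

    cm <- methods::as(Matrix::Matrix(t(counts), sparse = TRUE), "CsparseMatrix")
    dimnames(cm) <- list(gene_ids, sprintf("cell%05d", seq_len(n)))
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = cm),
      colData = S4Vectors::DataFrame(
        cluster = factor(cluster - 1L),
        condition = factor(paste0("cond", condition)),
        row.names = colnames(cm)))
    truth <- list(cluster = cluster - 1L,
                  condition = condition,
                  library_factor = libf,
                  baseline = setNames(lambda, gene_ids),
                  activity = z,
                  marker_of = setNames(marker_of, gene_ids),
                  module_of = setNames(module_of, gene_ids),
                  loading = setNames(loading, gene_ids),
                  hub_gene = gene_ids[hub_of],
                  sparse_active = sparse_active,
                  module_genes = lapply(seq_along(spec$modules), function(m)
                    gene_ids[which(module_of == m)]))
    list(sce = sce, truth = truth, spec = spec)
  })
}

#' Reference synthetic fixture
#'
#' A ~3,000-cell x 1,200-gene dataset with 5 clusters, 3 conditions and 6
#' planted modules mirroring the statistical situations the toolkit is
#' meant to distinguish: a module conserved across conditions, a
#' condition-specific module, a sparse module active in ~5% of cells across
#' all clusters (a program invisible to clustering), a module with graded
#' activity across clusters, and a pair of modules sharing a latent factor,
#' one of which (the "homeostatic" member) is down-shifted in the perturbed
#' condition.
#'
#' @param seed RNG seed.
#' @param n_cells,n_genes optional size overrides for quicker tests.
#' @return as \code{simulateCounts()}.
#' @export
syntheticFixture <- function(seed = 7, n_cells = 3000, n_genes = 1200) {
  lr <- c(0.4, 0.75)
  modules <- list(
    conserved = list(n_genes = 60, activity = "shared", mu = 0,
                     loading_range = lr),
    condition_specific = list(n_genes = 50, activity = "condition",
                              mu = c(0, 0, 1.0), loading_range = lr),
    sparse = list(n_genes = 40, activity = "sparse", sparse_fraction = 0.05,
                  hub_loading = 0.55, loading_range = c(0.35, 0.55)),
    graded = list(n_genes = 50, activity = "graded",
                  mu = c(0, 0.25, 0.5, 0.75, 1.0), loading_range = lr),
    latent_a = list(n_genes = 40, activity = "shared", mu = 0,
                    latent_factor = 1, latent_weight = 0.95,
                    loading_range = lr),
    homeostatic = list(n_genes = 40, activity = "shared", mu = 0,
                       latent_factor = 1, latent_weight = 0.95,
                       condition_shift = c(0, 0, -1.0), loading_range = lr)
  )
  spec <- syntheticSpec(
    n_cells = n_cells, n_genes = n_genes,
    cluster_props = c(0.30, 0.25, 0.20, 0.15, 0.10),
    condition_props = c(1 / 3, 1 / 3, 1 / 3),
    n_markers = 50, marker_effect = 3.0,
    modules = modules, module_meanlog = log(2), seed = seed)
  simulateCounts(spec)
}

#' Null fixture with no planted structure
#'
#' Same count model but zero marker effects and zero modules; used for
#' type-I error and grey-module calibration.
#'
#' @param seed RNG seed.
#' @param n_cells,n_genes size.
#' @export
nullFixture <- function(seed = 1, n_cells = 800, n_genes = 400) {
  spec <- syntheticSpec(n_cells = n_cells, n_genes = n_genes,
                        cluster_props = 1, condition_props = 1,
                        n_markers = 0, marker_effect = 0,
                        modules = list(), seed = seed)
  simulateCounts(spec)
}
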