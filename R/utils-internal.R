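# Internal helpers shared across modules. Not exported.

# Row variances with the n-1 denominator, tolerant of sparse input.
.rowVars <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("variance undefined for fewer than 2 samples")
  mu <- Matrix::rowMeans(m)
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

.colVars <- function(m) .rowVars(Matrix::t(m))

# Evaluate expr under a private RNG stream, restoring global state afterwards.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Standard WGCNA module colour sequence; labels beyond it fall back to
# "module_<k>".
.moduleColorSequence <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
)

.moduleColor <- function(i) {
  ifelse(i <= length(.moduleColorSequence),
         .moduleColorSequence[pmin(i, length(.moduleColorSequence))],
         paste0("module_", i))
}

# Disambiguate duplicated ids with "-1", "-2", ... suffixes in file order;
# unique ids are left untouched.
.disambiguateIds <- function(ids) {
  dup <- ids[duplicated(ids)]
  if (length(dup) == 0L) return(ids)
  for (d in unique(dup)) {
    idx <- which(ids == d)
    ids[idx] <- paste0(d, "-", seq_along(idx))
  }
  ids
}

.checkSymmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop(what, " must be symmetric")
  invisible(TRUE)
}

# Two-sided Wilcoxon rank-sum z statistic via the normal approximation with
# tie and continuity corrections. `ranks` are ranks over the pooled sample,
# `tie_term` is sum(t^3 - t) over tie groups, `in_idx` a logical mask.
.wilcoxZ <- function(ranks, tie_term, in_idx) {
  n <- length(ranks)
  n1 <- sum(in_idx)
  n2 <- n - n1
  r1 <- sum(ranks[in_idx])
  mu <- n1 * (n + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(c(z = 0, p = 1))
  diff <- r1 - mu
  cc <- sign(diff) * 0.5
  z <- (diff - cc) / sqrt(sigma2)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

.tieTerm <- function(x) {
  t <- tabulate(match(x, unique(x)))
  sum(t^3 - t)
}

# Extract a genes x samples numeric matrix from the containers the toolkit
# uses (SingleCellExperiment log layer, MetacellExperiment, plain matrix).
.exprMatrix <- function(x, layer = "logcounts") {
  if (is(x, "MetacellExperiment")) {
    as.matrix(SummarizedExperiment::assay(x, "meta"))
  } else if (is(x, "SummarizedExperiment")) {
    if (!layer %in% SummarizedExperiment::assayNames(x))
      stop("layer '", layer, "' not present; run the preprocessing steps first")
    as.matrix(SummarizedExperiment::assay(x, layer))
  } else if (is.matrix(x)) {
    x
  } else {
    as.matrix(x)
  }
}
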