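#' Accessors for toolkit classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the corresponding class.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("corrMatrix", function(x, ...) standardGeneric("corrMatrix"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x, ...) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("tomMatrix", function(x, ...) standardGeneric("tomMatrix"))

#' @rdname accessors
#' @export
setGeneric("dissimMatrix", function(x, ...) standardGeneric("dissimMatrix"))

#' @rdname accessors
#' @export
setGeneric("softPower", function(x, ...) standardGeneric("softPower"))

#' @rdname accessors
#' @export
setGeneric("powerScan", function(x, ...) standardGeneric("powerScan"))

#' @rdname accessors
#' @export
setGeneric("networkGenes", function(x, ...) standardGeneric("networkGenes"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x, ...) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x, module, ...) standardGeneric("moduleGenes"))

#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(x, ...) standardGeneric("moduleSizes"))

#' @rdname accessors
#' @export
setGeneric("eigengeneValues", function(x, ...) standardGeneric("eigengeneValues"))

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(x, ...) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x, ...) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("aggregationMode", function(x, ...) standardGeneric("aggregationMode"))

#' @rdname accessors
#' @export
setGeneric("geneSetList", function(x, ...) standardGeneric("geneSetList"))

#' @rdname accessors
#' @export
setGeneric("setBackground", function(x, ...) standardGeneric("setBackground"))

#' @rdname accessors
#' @export
setGeneric("preservationStats", function(x, ...) standardGeneric("preservationStats"))

# ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("corrMatrix", "CoexpressionNetwork", function(x, ...) x@corr)

#' @rdname accessors
#' @param beta soft power; defaults to the network's stored value.
#' @export
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x, beta = x@beta, ...) {
  softAdjacency(x@corr, beta)
})

#' @rdname accessors
#' @export
setMethod("tomMatrix", "CoexpressionNetwork", function(x, ...) x@tom)

#' @rdname accessors
#' @export
setMethod("dissimMatrix", "CoexpressionNetwork", function(x, ...) {
  d <- 1 - x@tom
  diag(d) <- 0
  d
})

#' @rdname accessors
#' @export
setMethod("softPower", "CoexpressionNetwork", function(x, ...) x@beta)

#' @rdname accessors
#' @export
setMethod("powerScan", "CoexpressionNetwork", function(x, ...) x@powerScan)

#' @rdname accessors
#' @export
setMethod("networkGenes", "CoexpressionNetwork", function(x, ...) x@genes)

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleSet", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("moduleGenes", "ModuleSet", function(x, module, ...) {
  names(x@labels)[x@labels == module]
})

#' @rdname accessors
#' @export
setMethod("moduleSizes", "ModuleSet", function(x, ...) {
  tab <- table(x@labels[x@labels != "grey"])
  sort(tab, decreasing = TRUE)
})

#' @rdname accessors
#' @export
setMethod("eigengeneValues", "EigengeneMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "EigengeneMatrix", function(x, ...) x@varianceExplained)

#' @rdname accessors
#' @export
setMethod("membership", "MetacellExperiment", function(x, ...) {
  S4Vectors::metadata(x)$membership
})

#' @rdname accessors
#' @export
setMethod("aggregationMode", "MetacellExperiment", function(x, ...) {
  S4Vectors::metadata(x)$aggregation
})

#' @rdname accessors
#' @export
setMethod("geneSetList", "GeneSets", function(x, ...) x@sets)

#' @rdname accessors
#' @export
setMethod("setBackground", "GeneSets", function(x, ...) x@background)

#' @rdname accessors
#' @export
setMethod("preservationStats", "PreservationReport", function(x, ...) x@stats)

# ---- show methods --------------------------------------------------------

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", length(object@genes), "genes,",
      object@method, "correlation, beta =", object@beta, "\n")
})

setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat("ModuleSet:", length(sz), "modules over", length(object@labels),
      "genes (", sum(object@labels == "grey"), "grey )\n")
  if (length(sz)) print(sz)
})

setMethod("show", "EigengeneMatrix", function(object) {
  cat("EigengeneMatrix:", nrow(object@values), object@space, "x",
      ncol(object@values), "modules\n")
})

setMethod("show", "GeneSets", function(object) {
  cat("GeneSets:", length(object@sets), "sets")
  if (length(object@background)) cat(",", length(object@background), "background genes")
  cat("\n")
})

setMethod("show", "PreservationReport", function(object) {
  cat("PreservationReport:", nrow(object@stats), "modules,",
      object@nPerm, "permutations (seed", object@seed, ")\n")
  print(object@stats[, c("module", "Z_density", "Z_connectivity",
                         "Z_summary", "median_rank")])
})
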