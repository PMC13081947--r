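#' Read a 10x-style MatrixMarket triplet directory
#'
#' Reads \code{matrix.mtx[.gz]} together with \code{barcodes.tsv[.gz]} and
#' \code{features.tsv[.gz]} (or \code{genes.tsv}) and returns a
#' \linkS4class{SingleCellExperiment} with a sparse \code{counts} assay in
#' the genes x cells orientation, whatever the on-disk orientation was.
#' Orientation is decided by matching matrix dimensions against the axis
#' files; a square matrix defaults to the 10x convention (genes as rows).
#'
#' Duplicate feature or barcode ids are disambiguated deterministically with
#' suffixes "-1", "-2", ... in file order. Features files with multiple
#' columns use the second column (the symbol) as the gene id.
#'
#' @param dir_path directory containing the triplet.
#' @return a \linkS4class{SingleCellExperiment}.
#' @export
readMTXTriplet <- function(dir_path) {
  findFile <- function(bases) {
    for (b in bases) for (ext in c("", ".gz")) {
      f <- file.path(dir_path, paste0(b, ext))
      if (file.exists(f)) return(f)
    }
    stop("no file matching '", paste(bases, collapse = "' or '"),
         "' found in ", dir_path)
  }
  mtx_file <- findFile("matrix.mtx")
  bc_file  <- findFile("barcodes.tsv")
  ft_file  <- findFile(c("features.tsv", "genes.tsv"))

  readLinesAny <- function(f) {
    con <- if (grepl("\\.gz$", f)) gzfile(f, "rt") else file(f, "rt")
    on.exit(close(con))
    readLines(con)
  }
  m <- if (grepl("\\.gz$", mtx_file)) {
    con <- gzfile(mtx_file, "rt"); on.exit(close(con), add = TRUE)
    Matrix::readMM(con)
  } else Matrix::readMM(mtx_file)

  barcodes <- readLinesAny(bc_file)
  barcodes <- barcodes[nzchar(barcodes)]
  ft_lines <- readLinesAny(ft_file)
  ft_lines <- ft_lines[nzchar(ft_lines)]
  ft_fields <- strsplit(ft_lines, "\t", fixed = TRUE)
  features <- vapply(ft_fields, function(f) {
    if (length(f) >= 2L) f[[2]] else f[[1]]
  }, character(1))

  nb <- length(barcodes); nf <- length(features)
  if (nrow(m) == nf && ncol(m) == nb) {
    # on-disk 10x convention, already genes x cells
  } else if (nrow(m) == nb && ncol(m) == nf) {
    m <- Matrix::t(m)
  } else {
    bad <- if (!nf %in% dim(m)) basename(ft_file) else basename(bc_file)
    stop("format error in '", bad, "': matrix is ", nrow(m), " x ", ncol(m),
         " but features=", nf, ", barcodes=", nb)
  }
  m <- methods::as(m, "CsparseMatrix")
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop("format error in '", basename(mtx_file),
         "': counts must be non-negative integers")
  dimnames(m) <- list(.disambiguateIds(features), .disambiguateIds(barcodes))
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a counts matrix as a MatrixMarket triplet
#'
#' Inverse of \code{readMTXTriplet()}: writes \code{matrix.mtx} (genes x
#' cells, the 10x convention), \code{features.tsv} and \code{barcodes.tsv}.
#'
#' @param sce a SingleCellExperiment with a \code{counts} assay.
#' @param dir_path output directory (created if missing).
#' @export
writeMTXTriplet <- function(sce, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir_path, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir_path, "features.tsv"))
  writeLines(colnames(sce), file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a dense delimited count table
#'
#' @param path TSV/CSV file with a header row and an id column first.
#' @param orientation \code{"cells_by_genes"} (rows are cells) or
#'   \code{"genes_by_cells"}.
#' @return a \linkS4class{SingleCellExperiment} (genes x cells).
#' @export
readDenseTable <- function(path,
                           orientation = c("cells_by_genes", "genes_by_cells")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               colClasses = "character"),
    error = function(e) stop("format error reading ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("format error: ", path, " has no data rows/columns")
  ids <- .disambiguateIds(df[[1]])
  num <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(num), ncol(num),
              dimnames = list(ids, .disambiguateIds(colnames(num))))
  for (j in seq_len(ncol(num))) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]) & nzchar(num[[j]]))
    if (length(bad))
      stop("format error: non-numeric value at row ", bad[1], ", column ",
           colnames(num)[j], " of ", path)
    m[, j] <- v
  }
  if (anyNA(m)) stop("format error: missing values in ", path)
  if (orientation == "cells_by_genes") m <- t(m)
  if (any(m < 0) || any(m != round(m)))
    stop("format error: counts must be non-negative integers in ", path)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                       "CsparseMatrix")))
}

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, member genes.
#' Duplicate genes within a line are removed, preserving first-seen order.
#'
#' @param path GMT file.
#' @return a \linkS4class{GeneSets} object.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("format error: GMT line ", i, " has fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[f[1]]] <- genes
    descs[f[1]] <- f[2]
  }
  methods::new("GeneSets", sets = sets, descriptions = descs,
               background = character(0))
}

#' Write gene sets as GMT
#'
#' @param x a \linkS4class{GeneSets} or named list of gene vectors.
#' @param path output file.
#' @export
writeGMT <- function(x, path) {
  sets <- if (is(x, "GeneSets")) geneSetList(x) else x
  descs <- if (is(x, "GeneSets")) x@descriptions else
    setNames(rep(".", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, if (is.na(descs[nm])) "." else descs[nm], sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular result as TSV
#'
#' Matrices are written with their row names in a leading \code{id} column;
#' data frames as-is with a header. Numeric values round-trip through
#' \code{readTSV()} to better than 1e-12.
#'
#' @param obj data.frame or matrix.
#' @param path output file.
#' @export
writeTSV <- function(obj, path) {
  if (is.matrix(obj)) {
    df <- data.frame(id = rownames(obj), obj, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else if (is.data.frame(obj)) {
    df <- obj
  } else stop("writeTSV expects a matrix or data.frame")
  con <- tryCatch(file(path, "wt"),
                  error = function(e) stop("I/O error opening ", path))
  on.exit(close(con))
  # full double precision so that read-back reproduces values exactly enough
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by \code{writeTSV()}
#'
#' @param path input file.
#' @param rownames_col optional column to use as matrix row names; when
#'   given, a numeric matrix is returned instead of a data.frame.
#' @export
readTSV <- function(path, rownames_col = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!is.null(rownames_col)) {
    rn <- df[[rownames_col]]
    m <- as.matrix(df[, setdiff(colnames(df), rownames_col), drop = FALSE])
    rownames(m) <- rn
    storage.mode(m) <- "double"
    return(m)
  }
  df
}
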