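#' Read an expression matrix
#'
#' Supported formats: Matrix Market (\code{.mtx}) with \code{genes.tsv} /
#' \code{barcodes.tsv} sidecars, and dense CSV/TSV with a header row and
#' an identifier column. The orientation flag says which dimension is
#' genes on disk; the returned container is always genes x cells.
#'
#' @param path matrix file.
#' @param format \code{"mtx"}, \code{"csv"} or \code{"tsv"} (guessed from
#'   the extension by default).
#' @param orientation \code{"genes_by_cells"} (default) or
#'   \code{"cells_by_genes"}.
#' @param genes,cells sidecar paths for MTX (default \code{genes.tsv} and
#'   \code{barcodes.tsv} next to the matrix).
#' @return a \linkS4class{SingleCellExperiment} with assay \code{"counts"}
#' @export
readExpressionMatrix <- function(path,
                                 format = c("auto", "mtx", "csv", "tsv"),
                                 orientation = c("genes_by_cells",
                                                 "cells_by_genes"),
                                 genes = NULL, cells = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv",
                     txt = "tsv",
                     stopf("cannot guess format from extension '%s'", ext))
  }
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stopf("malformed MTX '%s': %s", path,
                                            conditionMessage(e)))
    dir <- dirname(path)
    genes <- genes %||% file.path(dir, "genes.tsv")
    cells <- cells %||% file.path(dir, "barcodes.tsv")
    gid <- read.table(genes, header = FALSE, sep = "\t",
                      colClasses = "character")[[1]]
    cid <- read.table(cells, header = FALSE, sep = "\t",
                      colClasses = "character")[[1]]
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
    if (nrow(m) != length(gid) || ncol(m) != length(cid))
      stopf("MTX dimensions (%d x %d) do not match sidecars (%d genes, %d cells)",
            nrow(m), ncol(m), length(gid), length(cid))
    return(newExpressionMatrix(m, gid, cid))
  }
  sep <- if (format == "csv") "," else "\t"
  first <- readLines(path, n = 1L)
  if (!grepl(sep, first, fixed = TRUE))
    stopf("malformed header in '%s' (line 1: no '%s' separator)", path, sep)
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                   check.names = FALSE)
  m <- as.matrix(df)
  if (orientation == "cells_by_genes") m <- t(m)
  newExpressionMatrix(m, rownames(m), colnames(m))
}

#' Write an expression layer
#'
#' @param sce a \linkS4class{SingleCellExperiment}.
#' @param path output path; \code{.mtx} writes Matrix Market plus
#'   \code{genes.tsv} / \code{barcodes.tsv} sidecars, \code{.csv} /
#'   \code{.tsv} write a dense table (genes as rows).
#' @param layer assay to write (default \code{"counts"}).
#' @return the path, invisibly
#' @export
writeExpressionMatrix <- function(sce, path, layer = "counts") {
  m <- .get_assay(sce, layer, "writeExpressionMatrix")
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    dir <- dirname(path)
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- data.frame(gene = rownames(m), as.matrix(m), check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write an embedding as CSV
#' @param embedding cells x d matrix with cell ids as row names
#' @param path output path
#' @export
writeEmbedding <- function(embedding, path) {
  df <- data.frame(cell_id = rownames(embedding), embedding,
                   check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
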