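#' Create an expression container
#'
#' Wraps a genes x cells count matrix in a
#' \linkS4class{SingleCellExperiment} with assay \code{"counts"}. Gene and
#' cell identifiers must be unique; raw counts must be non-negative.
#'
#' @param counts genes x cells matrix (dense or \pkg{Matrix} sparse).
#' @param gene_ids,cell_ids identifiers; default taken from dimnames.
#' @return a \linkS4class{SingleCellExperiment}
#' @export
newExpressionMatrix <- function(counts, gene_ids = rownames(counts),
                                cell_ids = colnames(counts)) {
  assert_matrix_like(counts, "counts")
  if (is.null(gene_ids) || is.null(cell_ids))
    stopf("gene and cell identifiers are required")
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stopf("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stopf("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stopf("duplicate cell identifiers")
  if (min(counts) < 0) stopf("raw counts contain negative entries")
  dimnames(counts) <- list(gene_ids, cell_ids)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

.get_assay <- function(sce, layer, caller) {
  if (!layer %in% SummarizedExperiment::assayNames(sce))
    stopf("%s requires the '%s' assay; run the upstream step first",
          caller, layer)
  SummarizedExperiment::assay(sce, layer)
}

#' Library-size log-normalization
#'
#' Divides each cell's counts by the cell's total count, multiplies by
#' \code{scale_factor} and applies \code{log1p}. Cells with zero total pass
#' through as all-zero. Adds assay \code{"lognorm"}.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with assay
#'   \code{"counts"}.
#' @param scale_factor positive scale applied after library-size division
#'   (default 10000).
#' @return the container with assay \code{"lognorm"} added
#' @export
logNormalize <- function(sce, scale_factor = 1e4) {
  if (scale_factor <= 0) stopf("scale_factor must be positive")
  counts <- .get_assay(sce, "counts", "logNormalize")
  if (min(counts) < 0) stopf("raw counts contain negative entries")
  totals <- Matrix::colSums(counts)
  denom <- ifelse(totals > 0, totals, 1)  # all-zero cells stay all-zero
  if (methods::is(counts, "sparseMatrix")) {
    ln <- counts %*% Matrix::Diagonal(x = scale_factor / denom)
    ln@x <- log1p(ln@x)
  } else {
    ln <- log1p(sweep(counts, 2, scale_factor / denom, "*"))
  }
  dimnames(ln) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "lognorm") <- ln
  sce
}

#' Highly variable gene selection
#'
#' Keeps the \code{n_genes} genes with the largest variance of
#' log-normalized values, preserving the original gene order among those
#' selected. Ties at the cutoff are broken by lexicographically smaller
#' gene id. Optionally force-includes genes (e.g. genes of interest) that
#' fall below the cutoff, displacing the lowest-variance selections.
#'
#' @param sce container with assay \code{"lognorm"}.
#' @param n_genes number of genes to keep; must not exceed the number of
#'   genes present.
#' @param force_include character vector of gene ids always kept.
#' @return the container subset to the selected genes
#' @export
selectHVG <- function(sce, n_genes, force_include = character()) {
  ln <- .get_assay(sce, "lognorm", "selectHVG")
  N <- nrow(ln)
  if (n_genes > N) stopf("n_genes (%d) exceeds available genes (%d)",
                         n_genes, N)
  miss <- setdiff(force_include, rownames(ln))
  if (length(miss)) stopf("force_include genes absent: %s",
                          paste(miss, collapse = ", "))
  v <- row_vars(ln)
  ids <- rownames(ln)
  # rank by variance desc, ties by lexicographic gene id
  ord <- order(-v, ids)
  keep <- ids[ord[seq_len(n_genes)]]
  extra <- setdiff(force_include, keep)
  if (length(extra)) {
    # displace the lowest-variance selections that are not force-included
    droppable <- setdiff(rev(keep), force_include)
    keep <- setdiff(keep, droppable[seq_len(length(extra))])
    keep <- c(keep, extra)
  }
  sce[ids[ids %in% keep], ]
}

row_vars <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    n <- ncol(m)
    mu <- Matrix::rowMeans(m)
    (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
  } else {
    apply(m, 1, var)
  }
}

#' Per-gene scaling
#'
#' Centers each gene to mean zero and divides by its sample standard
#' deviation (denominator n-1). Constant genes map to all-zero rather than
#' erroring. Optionally truncates scaled values to \code{[-clip, clip]}.
#' Adds the dense assay \code{"scaled"}.
#'
#' @param sce container with assay \code{"lognorm"}.
#' @param clip positive truncation bound, or \code{NULL} (default) for no
#'   clipping.
#' @return the container with assay \code{"scaled"} added
#' @export
scaleGenes <- function(sce, clip = NULL) {
  ln <- as.matrix(.get_assay(sce, "lognorm", "scaleGenes"))
  mu <- rowMeans(ln)
  s <- apply(ln, 1, sd)
  s[s == 0 | is.na(s)] <- Inf  # constant genes -> zeros
  sc <- (ln - mu) / s
  if (!is.null(clip)) {
    if (clip <= 0) stopf("clip must be positive")
    sc[sc > clip] <- clip
    sc[sc < -clip] <- -clip
  }
  SummarizedExperiment::assay(sce, "scaled") <- sc
  sce
}

#' PCA baseline embedding
#'
#' Computes the top principal-component scores of the scaled matrix (cells
#' as observations) by exact singular value decomposition. This is the
#' 50-dimensional unsupervised baseline used both by the
#' regularization-decision procedure and for benchmarking. The sign of each
#' component is fixed so that the loading with the largest magnitude is
#' positive.
#'
#' @param sce container with assay \code{"scaled"}, or a cells x genes
#'   matrix of scaled values.
#' @param n_dims number of components (default 50, capped at the available
#'   rank by the caller).
#' @return cells x n_dims matrix of principal-component scores; when given
#'   a container, also stored as \code{reducedDim(sce, "PCA")} and the
#'   container is returned.
#' @export
pcaEmbed <- function(sce, n_dims = 50) {
  if (methods::is(sce, "SummarizedExperiment")) {
    x <- t(as.matrix(.get_assay(sce, "scaled", "pcaEmbed")))
    emb <- pcaEmbed(x, n_dims)
    SingleCellExperiment::reducedDim(sce, "PCA") <- emb
    return(sce)
  }
  x <- as.matrix(sce)
  if (n_dims > min(dim(x)))
    stopf("n_dims (%d) exceeds min(cells, genes) = %d", n_dims, min(dim(x)))
  ctr <- sweep(x, 2, colMeans(x))
  sv <- svd(ctr, nu = n_dims, nv = n_dims)
  if (n_dims > sum(sv$d > sv$d[1] * 1e-12))
    stopf("n_dims (%d) exceeds the numerical rank (%d)",
          n_dims, sum(sv$d > sv$d[1] * 1e-12))
  # fix signs: largest-magnitude loading positive
  for (j in seq_len(n_dims)) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) {
      sv$v[, j] <- -l
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_dims)], n_dims)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_dims))
  scores
}

#' Minimal preprocessing pipeline
#'
#' Convenience wrapper: log-normalize, select highly variable genes, scale,
#' and compute the PCA baseline embedding.
#'
#' @inheritParams logNormalize
#' @inheritParams selectHVG
#' @inheritParams scaleGenes
#' @param n_pcs dimensions of the PCA baseline (default 50; truncated to
#'   the available rank).
#' @return the processed \linkS4class{SingleCellExperiment}
#' @export
preprocess <- function(sce, scale_factor = 1e4, n_genes = min(nrow(sce), 1e4),
                       force_include = character(), clip = NULL, n_pcs = 50) {
  sce <- logNormalize(sce, scale_factor)
  sce <- selectHVG(sce, n_genes, force_include)
  sce <- scaleGenes(sce, clip)
  # cap the baseline dimensionality at the numerical rank
  x <- t(SummarizedExperiment::assay(sce, "scaled"))
  ctr <- sweep(x, 2, colMeans(x))
  d <- svd(ctr, nu = 0, nv = 0)$d
  rank <- sum(d > d[1] * 1e-12)
  pcaEmbed(sce, min(n_pcs, rank))
}
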