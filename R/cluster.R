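#' Shared nearest-neighbour graph clustering
#'
#' Builds a k-nearest-neighbour graph on Euclidean distances in the
#' embedding, re-weights edges by the Jaccard overlap of the two cells'
#' neighbourhoods (each neighbourhood includes the cell itself), prunes
#' weak edges, and partitions the graph by Louvain modularity
#' optimization. Defaults mirror the standard single-cell pipeline:
#' 20 neighbours, resolution 0.8, Jaccard pruning threshold 1/15.
#'
#' @param embedding cells x d numeric matrix with row names as cell ids.
#' @param n_neighbors neighbourhood size (must be < number of cells).
#' @param resolution Louvain resolution.
#' @param prune Jaccard threshold below which SNN edges are dropped.
#' @param seed integer seed for the community search.
#' @param method \code{"louvain"} (default) or \code{"leiden"}.
#' @return a [ClusterAssignment-class] with 0-based contiguous cluster ids
#' @export
snnCluster <- function(embedding, n_neighbors = 20, resolution = 0.8,
                       prune = 1 / 15, seed = 1L,
                       method = c("louvain", "leiden")) {
  method <- match.arg(method)
  embedding <- as.matrix(embedding)
  M <- nrow(embedding)
  if (M <= n_neighbors)
    stopf("need more cells (%d) than neighbours (%d)", M, n_neighbors)
  ids <- rownames(embedding) %||% paste0("cell", seq_len(M))

  nn <- knn_index(embedding, n_neighbors)
  # neighbourhood indicator (self included) as sparse pattern matrix
  ind <- Matrix::sparseMatrix(
    i = c(seq_len(M), as.vector(nn)),              # nn is column-major:
    j = c(seq_len(M), rep(seq_len(M), times = ncol(nn))),  # col l = l-th nbr
    x = 1, dims = c(M, M))
  ind@x[] <- 1
  shared <- Matrix::crossprod(ind)              # cells x cells shared counts
  k1 <- n_neighbors + 1L
  snn <- methods::as(shared, "TsparseMatrix")
  keep <- snn@i < snn@j
  i <- snn@i[keep] + 1L; j <- snn@j[keep] + 1L
  w <- snn@x[keep] / (2 * k1 - snn@x[keep])     # Jaccard from intersection
  ok <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = w[ok]),
    directed = FALSE, vertices = data.frame(name = seq_len(M)))
  memb <- with_seed(derive_seed(seed, "louvain"), {
    if (method == "louvain")
      igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
    else
      igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity",
        resolution_parameter = resolution))
  })
  cl <- as.integer(memb[as.character(seq_len(M))])
  cl <- as.integer(factor(cl)) - 1L             # contiguous, 0-based
  clusterAssignment(ids, cl,
    params = list(n_neighbors = n_neighbors, resolution = resolution,
                  metric = "euclidean", prune = prune, seed = seed,
                  method = method))
}

# indices of the n_nbr nearest neighbours (self excluded), M x n_nbr
knn_index <- function(x, n_nbr) {
  M <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(n_nbr)]))
}

#' Complete-linkage hierarchy of clusters over detection-rate profiles
#'
#' Builds each cluster's detection-rate vector over the genes of interest
#' (fraction of member cells with nonzero expression per gene), computes
#' pairwise distances as 1 - cosine similarity, agglomerates by
#' complete linkage, and cuts the tree into \code{n_groups} groups. A
#' cluster detecting none of the genes has a zero vector; it is assigned
#' its own group. Used e.g. to organise hormone-gene expression patterns
#' across islet cell clusters.
#'
#' @param sce container with assay \code{"lognorm"} (or the genes x cells
#'   matrix itself).
#' @param assignment a [ClusterAssignment-class].
#' @param genes genes of interest (character vector, present in the
#'   matrix).
#' @param n_groups number of groups to cut into.
#' @return integer vector mapping cluster id (names \code{"0"},
#'   \code{"1"}, ...) to group label \code{1..n_groups(+)}
#' @export
clusterGoiHierarchy <- function(sce, assignment, genes, n_groups) {
  rates <- detectionRates(sce, assignment, genes)   # genes x clusters
  k <- ncol(rates)
  if (n_groups < 1 || n_groups > k) stopf("n_groups must be in [1, k]")
  nz <- sqrt(colSums(rates^2))
  zero <- nz == 0
  active <- which(!zero)
  groups <- integer(k)
  if (length(active) >= 2) {
    r <- rates[, active, drop = FALSE]
    cs <- crossprod(r) / tcrossprod(nz[active])
    dmat <- as.dist(1 - cs)
    hc <- hclust(dmat, method = "complete")
    ng <- min(n_groups, length(active))
    groups[active] <- cutree(hc, k = ng)
  } else if (length(active) == 1) {
    groups[active] <- 1L
  }
  # zero-detection clusters get their own singleton groups
  next_g <- max(groups, 0L)
  for (z in which(zero)) {
    next_g <- next_g + 1L
    groups[z] <- next_g
  }
  setNames(groups, as.character(seq_len(k) - 1L))
}

#' Write / read cluster assignments as TSV
#' @param assignment a [ClusterAssignment-class]
#' @param path file path
#' @export
writeClusters <- function(assignment, path) {
  write.table(data.frame(cell_id = assignment@cell_ids,
                         cluster = assignment@cluster_of),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer"))
  clusterAssignment(df$cell_id, df$cluster)
}
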