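#' Quadratic distinctiveness transform
#'
#' \code{q(t) = 4 t (t - 1) + 1}: equals 1 at t = 0 and t = 1, and 0 at
#' t = 0.5. High when a rate is decisively on or off.
#'
#' @param t value(s) in \code{[0, 1]}.
#' @return value(s) in \code{[0, 1]}
#' @export
qScore <- function(t) {
  if (any(t < 0 | t > 1)) stopf("q() is defined on [0, 1]")
  4 * t * (t - 1) + 1
}

.lognorm_matrix <- function(sce, caller) {
  if (methods::is(sce, "SummarizedExperiment"))
    as.matrix(.get_assay(sce, "lognorm", caller))
  else as.matrix(sce)
}

.cluster_members <- function(assignment) {
  split(seq_along(assignment@cluster_of), assignment@cluster_of)
}

#' Per-cluster detection rates
#'
#' Fraction of cells in each cluster with a nonzero expression of each
#' gene.
#'
#' @param sce container with assay \code{"lognorm"} (or a genes x cells
#'   matrix).
#' @param assignment a [ClusterAssignment-class] over the same cells.
#' @param genes character vector of gene ids.
#' @return genes x clusters matrix of exact fractions in \code{[0, 1]}
#' @export
detectionRates <- function(sce, assignment, genes) {
  ln <- .lognorm_matrix(sce, "detectionRates")
  miss <- setdiff(genes, rownames(ln))
  if (length(miss)) stopf("genes absent: %s", paste(miss, collapse = ", "))
  members <- .cluster_members(assignment)
  out <- vapply(members, function(ix)
    rowMeans(ln[genes, ix, drop = FALSE] > 0), numeric(length(genes)))
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, names(members)))
  out
}

#' Gene-expression distinctiveness score
#'
#' For each gene of interest and cluster, multiplies a detection
#' distinctiveness score \code{T = q(detection rate)} with an expression
#' distinctiveness score \code{E = q(F(mean expression))}, where \code{F}
#' is the gene's empirical CDF over all cells (right-continuous, ties
#' counted as <=). The product is averaged over clusters per gene, and
#' over genes for the overall score \code{G}. High \code{G} means the
#' genes are cleanly on/off across clusters, which is robust to a cell
#' type being split over several clusters.
#'
#' @inheritParams detectionRates
#' @param mean_mode \code{"all"} (default): cluster mean over all member
#'   cells; \code{"expressing_only"}: mean over expressing cells only (the
#'   dot-plot convention), with \code{F(0)} used when no cell expresses.
#' @return list with \code{per_gene} (named vector) and \code{G} (overall
#'   mean), both in \code{[0, 1]}
#' @export
distinctiveness <- function(sce, assignment, genes,
                            mean_mode = c("all", "expressing_only")) {
  mean_mode <- match.arg(mean_mode)
  ln <- .lognorm_matrix(sce, "distinctiveness")
  miss <- setdiff(genes, rownames(ln))
  if (length(miss)) stopf("genes absent: %s", paste(miss, collapse = ", "))
  members <- .cluster_members(assignment)
  per_gene <- vapply(genes, function(g) {
    v <- ln[g, ]
    Fg <- ecdf(v)
    scores <- vapply(members, function(ix) {
      vi <- v[ix]
      t_ij <- mean(vi > 0)
      e_ij <- if (mean_mode == "all") mean(vi)
        else if (any(vi > 0)) mean(vi[vi > 0]) else 0
      qScore(t_ij) * qScore(Fg(e_ij))
    }, 0)
    mean(scores)
  }, 0)
  list(per_gene = per_gene, G = mean(per_gene))
}

.pair_dist <- function(a, b, metric, eps = 1e-12) {
  if (metric == "euclidean") sqrt(sum((a - b)^2))
  else 1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)) + eps)
}

.dist_matrix <- function(x, metric, eps = 1e-12) {
  if (metric == "euclidean") as.matrix(stats::dist(x))
  else {
    n <- sqrt(rowSums(x^2))
    1 - (x %*% t(x)) / (outer(n, n) + eps)
  }
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst compactness-to-separation ratio
#' \code{R_xy = (mean dist to centroid in x + mean dist to centroid in y) /
#' d(centroid_x, centroid_y)}. Centroids are arithmetic means of member
#' points under either metric. Lower is better.
#'
#' @param embedding cells x d matrix.
#' @param assignment a [ClusterAssignment-class] (k >= 2).
#' @param metric \code{"euclidean"} or \code{"cosine"}.
#' @return non-negative scalar
#' @export
daviesBouldin <- function(embedding, assignment,
                          metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  x <- as.matrix(embedding)
  members <- .cluster_members(assignment)
  k <- length(members)
  if (k < 2) stopf("Davies-Bouldin needs at least 2 clusters")
  cents <- matrix(unlist(lapply(members, function(ix)
    colMeans(x[ix, , drop = FALSE]))), nrow = k, byrow = TRUE)
  spread <- vapply(seq_len(k), function(j)
    mean(vapply(members[[j]], function(i)
      .pair_dist(x[i, ], cents[j, ], metric), 0)), 0)
  R <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) if (a != b) {
    sep <- .pair_dist(cents[a, ], cents[b, ], metric)
    if (sep == 0) stopf("coincident cluster centroids")
    R[a, b] <- (spread[a] + spread[b]) / sep
  }
  mean(vapply(seq_len(k), function(a) max(R[a, -a]), 0))
}

#' Average silhouette width
#'
#' For each cell, \code{s = (b - a) / max(a, b)} with \code{a} the mean
#' distance to the other cells of its cluster and \code{b} the smallest
#' mean distance to the cells of another cluster; the mean of \code{s}
#' over all cells. Singleton clusters contribute \code{s = 0}. Range
#' \code{[-1, 1]}; negative values signal cells closer to another cluster
#' than their own, e.g. under embedding distortion from
#' over-supervision.
#'
#' @inheritParams daviesBouldin
#' @return scalar in \code{[-1, 1]}
#' @export
silhouetteWidth <- function(embedding, assignment,
                            metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  x <- as.matrix(embedding)
  cl <- assignment@cluster_of
  if (assignment@k < 2) stopf("silhouette needs at least 2 clusters")
  D <- .dist_matrix(x, metric)
  sizes <- table(cl)
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- cl[i]
    n_own <- sizes[[as.character(own)]]
    if (n_own == 1L) return(0)
    a <- sum(D[i, cl == own]) / (n_own - 1)   # excludes self (D[i,i]=0)
    b <- min(vapply(setdiff(unique(cl), own), function(y)
      mean(D[i, cl == y]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Calinski-Harabasz index
#'
#' \code{((n - k)/(k - 1)) * sum_x n_x d(c_x, c)^2 / sum_x sum_i d(i,
#' c_x)^2} where \code{c_x} are cluster centroids and \code{c} the global
#' centroid. Higher is better.
#'
#' @inheritParams daviesBouldin
#' @return non-negative scalar
#' @export
calinskiHarabasz <- function(embedding, assignment,
                             metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  x <- as.matrix(embedding)
  members <- .cluster_members(assignment)
  k <- length(members)
  n <- nrow(x)
  if (k < 2 || n <= k) stopf("CHI needs k >= 2 and n > k")
  global <- colMeans(x)
  between <- 0; within <- 0
  for (j in seq_len(k)) {
    ix <- members[[j]]
    cj <- colMeans(x[ix, , drop = FALSE])
    between <- between + length(ix) * .pair_dist(cj, global, metric)^2
    within <- within +
      sum(vapply(ix, function(i) .pair_dist(x[i, ], cj, metric)^2, 0))
  }
  if (within == 0) stopf("zero within-cluster scatter")
  ((n - k) / (k - 1)) * between / within
}

#' Majority labeling of clusters
#'
#' A cluster is labeled by a reference cell type when at least 50 percent
#' of its cells carry that type (ties at exactly 50 percent qualify; if
#' two types tie, the lexicographically smaller name wins). Otherwise the
#' cluster is \code{"unannotated"}. Cells with missing reference labels
#' form their own \code{NA} category for the majority count but can never
#' label a cluster.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param labels character vector of reference cell types, aligned with
#'   the assignment's cells (NA allowed).
#' @return named character vector: cluster id -> label
#' @export
labelClusters <- function(assignment, labels) {
  stopifnot(length(labels) == length(assignment@cell_ids))
  members <- .cluster_members(assignment)
  out <- vapply(members, function(ix) {
    l <- labels[ix]
    l_known <- l[!is.na(l)]
    if (!length(l_known)) return("unannotated")
    tab <- table(l_known)
    frac <- tab / length(l)               # denominator: all cells in cluster
    top <- max(frac)
    if (top >= 0.5) sort(names(frac)[frac == top])[1] else "unannotated"
  }, "")
  setNames(out, names(members))
}

#' External validation scores
#'
#' Compares a clustering with reference cell-type labels. Per-type
#' precision, recall and F1 use [labelClusters()] majority labels: TP is
#' the proportion of cells of the type placed in clusters labeled by the
#' type, FP the proportion of other cells placed in such clusters, etc.;
#' F1 is 0 when precision + recall is 0. ARI uses the standard
#' pair-counting adjusted form, and NMI normalizes mutual information by
#' the average entropy of the two partitions (natural log). Cells with
#' missing reference labels are excluded from all scores.
#'
#' @inheritParams labelClusters
#' @return list with \code{per_type} (data.frame of precision, recall,
#'   F1), \code{ari}, \code{nmi}
#' @export
externalScores <- function(assignment, labels) {
  stopifnot(length(labels) == length(assignment@cell_ids))
  keep <- !is.na(labels)
  cl <- assignment@cluster_of[keep]
  ref <- as.character(labels[keep])
  cluster_label <- labelClusters(assignment, labels)
  cell_cluster_label <- cluster_label[as.character(cl)]
  types <- sort(unique(ref))
  n <- length(ref)
  per_type <- do.call(rbind, lapply(types, function(ty) {
    in_type <- ref == ty
    in_lab <- cell_cluster_label == ty
    tp <- sum(in_type & in_lab) / n
    fp <- sum(!in_type & in_lab) / n
    fn <- sum(in_type & !in_lab) / n
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(type = ty, precision = precision, recall = recall, f1 = f1)
  }))
  list(per_type = per_type, ari = adjustedRandIndex(cl, ref),
       nmi = normalizedMutualInfo(cl, ref))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, adjusted for chance:
#' \code{(RI - E[RI]) / (max(RI) - E[RI])}. 1 for identical partitions,
#' expected 0 for independent random ones.
#'
#' @param a,b two partitions of the same items (any label type).
#' @return scalar in \code{[-1, 1]}
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' \code{2 MI / (H(a) + H(b))} with natural logarithms. When both
#' partitions are trivial (zero entropy), defined as 1 if they are
#' identical partitions and 0 otherwise.
#'
#' @inheritParams adjustedRandIndex
#' @return scalar in \code{[0, 1]}
#' @export
normalizedMutualInfo <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha + hb == 0) return(as.numeric(length(unique(a)) == length(unique(b))))
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  as.numeric(2 * mi / (ha + hb))
}

#' Full evaluation report for an embedding and clustering
#'
#' @param embedding cells x d matrix.
#' @param assignment a [ClusterAssignment-class].
#' @param sce optional expression container (assay \code{"lognorm"}) for
#'   distinctiveness.
#' @param goi_genes optional genes of interest for distinctiveness.
#' @param labels optional reference labels for external scores.
#' @param metric distance metric for the internal measures.
#' @return an [EvaluationReport-class]
#' @export
evaluateEmbedding <- function(embedding, assignment, sce = NULL,
                              goi_genes = NULL, labels = NULL,
                              metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  scores <- list(
    dbi = daviesBouldin(embedding, assignment, metric),
    asw = silhouetteWidth(embedding, assignment, metric),
    chi = calinskiHarabasz(embedding, assignment, metric),
    n_clusters = nClusters(assignment))
  if (!is.null(sce) && !is.null(goi_genes)) {
    d <- distinctiveness(sce, assignment, goi_genes)
    scores$distinctiveness <- d$G
    scores$distinctiveness_per_gene <- d$per_gene
  }
  if (!is.null(labels)) {
    ext <- externalScores(assignment, labels)
    scores$ari <- ext$ari
    scores$nmi <- ext$nmi
    scores$f1_per_type <- setNames(ext$per_type$f1, ext$per_type$type)
  }
  methods::new("EvaluationReport", scores = scores,
               meta = list(metric = metric,
                           labeling = "majority >= 50 percent",
                           mean_mode = "all"))
}

#' Rank-sum marker test
#'
#' Plain two-sided Wilcoxon rank-sum comparison of a gene's
#' log-normalized expression between the cells of one cluster and all
#' other cells.
#'
#' @inheritParams detectionRates
#' @param gene single gene id.
#' @param cluster 0-based cluster id.
#' @return list with \code{p_value} and \code{log_fc} (difference of group
#'   means on the log scale)
#' @export
rankSumTest <- function(sce, assignment, gene, cluster) {
  ln <- .lognorm_matrix(sce, "rankSumTest")
  if (!gene %in% rownames(ln)) stopf("gene '%s' absent", gene)
  v <- ln[gene, ]
  in_cl <- assignment@cluster_of == cluster
  if (!any(in_cl) || all(in_cl)) stopf("cluster %d empty or universal", cluster)
  w <- wilcox.test(v[in_cl], v[!in_cl], exact = FALSE)
  list(p_value = w$p.value, log_fc = mean(v[in_cl]) - mean(v[!in_cl]))
}
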