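# Independent brute-force oracles used to pin the evaluation statistics,
# plus small fixture builders shared across test files.

pair_dist_o <- function(a, b, metric = "euclidean") {
  if (metric == "euclidean") sqrt(sum((a - b)^2))
  else 1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)) + 1e-12)
}

oracle_dbi <- function(x, cl, metric = "euclidean") {
  ks <- sort(unique(cl))
  cents <- lapply(ks, function(k) colMeans(x[cl == k, , drop = FALSE]))
  spread <- vapply(seq_along(ks), function(j) {
    pts <- x[cl == ks[j], , drop = FALSE]
    mean(apply(pts, 1, pair_dist_o, b = cents[[j]], metric = metric))
  }, 0)
  worst <- vapply(seq_along(ks), function(a) {
    max(vapply(seq_along(ks)[-a], function(b)
      (spread[a] + spread[b]) /
        pair_dist_o(cents[[a]], cents[[b]], metric), 0))
  }, 0)
  mean(worst)
}

oracle_asw <- function(x, cl, metric = "euclidean") {
  n <- nrow(x)
  s <- vapply(seq_len(n), function(i) {
    own <- cl[i]
    mine <- which(cl == own & seq_len(n) != i)
    if (!length(mine)) return(0)
    a <- mean(vapply(mine, function(j) pair_dist_o(x[i, ], x[j, ], metric), 0))
    b <- min(vapply(setdiff(unique(cl), own), function(k) {
      other <- which(cl == k)
      mean(vapply(other, function(j) pair_dist_o(x[i, ], x[j, ], metric), 0))
    }, 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

oracle_chi <- function(x, cl, metric = "euclidean") {
  n <- nrow(x); ks <- sort(unique(cl)); k <- length(ks)
  global <- colMeans(x)
  between <- 0; within <- 0
  for (kk in ks) {
    pts <- x[cl == kk, , drop = FALSE]
    cj <- colMeans(pts)
    between <- between + nrow(pts) * pair_dist_o(cj, global, metric)^2
    within <- within + sum(apply(pts, 1, pair_dist_o, b = cj,
                                 metric = metric)^2)
  }
  ((n - k) / (k - 1)) * between / within
}

# pair-by-pair Rand-index based ARI
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  agree <- sum(same_a & same_b)
  na_ <- sum(same_a); nb_ <- sum(same_b); tot <- length(same_a)
  expected <- na_ * nb_ / tot
  maxi <- (na_ + nb_) / 2
  if (maxi == expected) return(0)
  (agree - expected) / (maxi - expected)
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  pj <- table(a) / n; pk <- table(b) / n
  ha <- -sum(pj * log(pj)); hb <- -sum(pk * log(pk))
  if (ha + hb == 0) return(as.numeric(length(unique(a)) == length(unique(b))))
  mi <- 0
  for (x in names(pj)) for (y in names(pk)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (pj[[x]] * pk[[y]]))
  }
  2 * mi / (ha + hb)
}

# exhaustive complete-linkage agglomeration over <= 12 items
oracle_complete_link_groups <- function(d, n_groups) {
  k <- nrow(d)
  groups <- as.list(seq_len(k))
  while (length(groups) > n_groups) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) for (b in seq_along(groups)) if (a < b) {
      dd <- max(d[groups[[a]], groups[[b]]])
      if (dd < best[1]) best <- c(dd, a, b)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  out <- integer(k)
  for (g in seq_along(groups)) out[groups[[g]]] <- g
  out
}

# exact 1-D two-sample W2 by order statistics
oracle_w2_1d <- function(a, b) sqrt(mean((sort(a) - sort(b))^2))

# tiny expression container from a genes x cells matrix
tiny_sce <- function(m, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  newExpressionMatrix(matrix(m, nrow(m), ncol(m),
                             dimnames = list(genes, cells)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_assignment <- function(cl, ids = NULL) {
  ids <- ids %||% sprintf("c%02d", seq_along(cl))
  sakura:::clusterAssignment(ids, as.integer(cl))
}

# small two-population count simulation used by several training tests
small_sim <- function(n_cells = 300, n_genes = 60, seed = 11,
                      lfc = 2, n_markers = 8) {
  markers <- sprintf("g%04d", seq_len(n_markers))
  params <- simulationParams(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    populations = data.frame(name = c("p1", "p2"), fraction = c(0.6, 0.4),
                             parent = NA_character_),
    log_fold_changes = list(p2 = setNames(rep(lfc, n_markers), markers)),
    seed = seed)
  sim <- simulateCounts(params)
  sim$markers <- markers
  sim
}
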