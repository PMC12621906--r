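test_that("the quadratic distinctiveness transform hits its anchor points", {
  expect_equal(qScore(0), 1)
  expect_equal(qScore(0.5), 0)
  expect_equal(qScore(1), 1)
  expect_error(qScore(1.2), "\\[0, 1\\]")
  t <- seq(0, 1, 0.05)
  expect_true(all(qScore(t) >= 0 & qScore(t) <= 1))
})

test_that("detection rates are exact per-cluster fractions", {
  ln <- rbind(g1 = c(0, 1, 2, 0, 0, 3), g2 = c(1, 1, 1, 0, 0, 0))
  asg <- make_assignment(c(0, 0, 0, 1, 1, 1))
  r <- detectionRates(ln, asg, c("g1", "g2"))
  expect_equal(r["g1", ], c("0" = 2 / 3, "1" = 1 / 3))
  expect_equal(r["g2", ], c("0" = 1, "1" = 0))
  expect_error(detectionRates(ln, asg, "nope"), "absent")
})

test_that("distinctiveness reproduces the two-cluster hand-walk and its
           degenerate case", {
  # 4 cells, 2 clusters; gene 2.0 in cluster A, 0 in cluster B
  ln <- matrix(c(2, 2, 0, 0), 1, dimnames = list("g", sprintf("c%d", 1:4)))
  asg <- make_assignment(c(0, 0, 1, 1))
  d <- distinctiveness(ln, asg, "g")
  # t_A = 1, t_B = 0 => T = 1 both; F(2) = 1 => E_A = 1; F(0) = 0.5 => E_B = 0
  expect_equal(d$G, 0.5)
  expect_equal(unname(d$per_gene), 0.5)

  # identical value everywhere, single cluster: F(e) = 1, t = 1 => G = 1
  ln2 <- matrix(1, 1, 4, dimnames = list("g", sprintf("c%d", 1:4)))
  expect_equal(distinctiveness(ln2, make_assignment(rep(0, 4)), "g")$G, 1)

  # range stays within [0, 1] on random inputs
  set.seed(6)
  ln3 <- matrix(rpois(5 * 40, 1), 5,
                dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:40)))
  asg3 <- make_assignment(sample(0:3, 40, replace = TRUE))
  g3 <- distinctiveness(ln3, asg3, sprintf("g%d", 1:5))$G
  expect_gte(g3, 0); expect_lte(g3, 1)
})

test_that("distinctiveness is invariant to relabeling, duplication, and
           splitting a cluster into identical halves", {
  set.seed(11)
  ln <- matrix(rpois(4 * 60, 1.2), 4,
               dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:60)))
  cl <- sample(0:2, 60, replace = TRUE)
  base <- distinctiveness(ln, make_assignment(cl), sprintf("g%d", 1:4))$G

  # relabel clusters
  perm <- c(2, 0, 1)
  expect_equal(distinctiveness(ln, make_assignment(perm[cl + 1]),
                               sprintf("g%d", 1:4))$G, base)

  # duplicate every cell
  ln2 <- cbind(ln, ln); colnames(ln2) <- sprintf("c%d", 1:120)
  expect_equal(distinctiveness(ln2, make_assignment(c(cl, cl)),
                               sprintf("g%d", 1:4))$G, base)

  # splitting a cluster into two identical halves leaves that cluster's
  # detection rate (hence T) and mean expression (hence E) exactly
  # unchanged in both halves
  both <- cbind(ln[, cl == 0], ln[, cl == 0], ln[, cl != 0])
  colnames(both) <- sprintf("c%d", seq_len(ncol(both)))
  n0 <- sum(cl == 0)
  cl_split <- c(rep(0, n0), rep(3, n0), cl[cl != 0])
  r1 <- detectionRates(both, make_assignment(cl_split), sprintf("g%d", 1:4))
  r0 <- detectionRates(ln, make_assignment(cl), sprintf("g%d", 1:4))
  expect_equal(r1[, "0"], r1[, "3"])
  expect_equal(unname(r1[, "0"]), unname(r0[, "0"]))

  # splitting every cluster into identical halves leaves G exactly equal
  split_all <- c(cl, cl + 3)
  expect_equal(distinctiveness(ln2, make_assignment(split_all),
                               sprintf("g%d", 1:4))$G, base)
})

test_that("Davies-Bouldin matches hand computation and the brute-force
           oracle", {
  # 1-D clusters {0,2} and {10,12}: R = (1+1)/10 = 0.2
  x <- matrix(c(0, 2, 10, 12), 4, 1)
  asg <- make_assignment(c(0, 0, 1, 1))
  expect_equal(daviesBouldin(x, asg), 0.2)

  # two singleton clusters: zero compactness
  expect_equal(daviesBouldin(matrix(c(0, 5), 2, 1),
                             make_assignment(c(0, 1))), 0)

  # coincident centroids are rejected (division by zero in the ratio)
  xc <- matrix(c(0, 1, 0, 1), 4, 1)
  expect_error(daviesBouldin(xc, make_assignment(c(0, 0, 1, 1))),
               "coincident")
})

test_that("internal validation measures equal brute-force oracles on random
           instances", {
  set.seed(14)
  for (r in 1:25) {
    n <- sample(15:30, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * 3), n, 3) +
      3 * matrix(rnorm(k * 3), k, 3)[rep_len(seq_len(k), n), ]
    cl <- rep_len(seq_len(k) - 1L, n)
    asg <- make_assignment(cl)
    metric <- if (r %% 2) "euclidean" else "cosine"
    expect_equal(daviesBouldin(x, asg, metric), oracle_dbi(x, cl, metric),
                 tolerance = 1e-9)
    expect_equal(silhouetteWidth(x, asg, metric), oracle_asw(x, cl, metric),
                 tolerance = 1e-9)
    expect_equal(calinskiHarabasz(x, asg, metric), oracle_chi(x, cl, metric),
                 tolerance = 1e-9)
  }
})

test_that("silhouette reproduces the hand case, the interleaved null and the
           ideal limit", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  asg <- make_assignment(c(0, 0, 1, 1))
  a <- 1; b <- (10 + sqrt(101)) / 2
  expect_equal(silhouetteWidth(x, asg), (b - a) / b, tolerance = 1e-12)
  expect_equal(round(silhouetteWidth(x, asg), 4), 0.9002)

  for (s in 1:3) {
    set.seed(200 + s)
    cloud <- matrix(rnorm(80 * 2), 80, 2)
    expect_lt(abs(silhouetteWidth(cloud,
                                  make_assignment(rep(0:1, 40)))), 0.1)
  }

  set.seed(3)
  tight <- do.call(rbind, lapply(0:3, function(k)
    matrix(rnorm(20 * 2, mean = 100 * k, sd = 0.5), 20, 2)))
  expect_gt(silhouetteWidth(tight, make_assignment(rep(0:3, each = 20))),
            0.95)
  expect_error(silhouetteWidth(x, make_assignment(rep(0, 4))), "2 clusters")
})

test_that("silhouette agrees with the cluster package on a random instance", {
  skip_if_not_installed("cluster")
  set.seed(9)
  x <- matrix(rnorm(40 * 3), 40, 3)
  cl <- sample(0:2, 40, replace = TRUE)
  sil <- cluster::silhouette(cl + 1, dist(x))
  expect_equal(silhouetteWidth(x, make_assignment(cl)),
               mean(sil[, "sil_width"]), tolerance = 1e-9)
})

test_that("Calinski-Harabasz matches hand computation and is scale
           invariant", {
  x <- matrix(c(0, 2, 10, 12), 4, 1)
  asg <- make_assignment(c(0, 0, 1, 1))
  expect_equal(calinskiHarabasz(x, asg), 50)
  expect_equal(calinskiHarabasz(7 * x, asg), 50)
  expect_error(calinskiHarabasz(matrix(c(0, 0, 1, 1), 4, 1),
                                make_assignment(c(0, 0, 1, 1))), "scatter")
})

test_that("majority labeling applies the >= 50 percent rule with its
           tie-break", {
  asg <- make_assignment(rep(0, 5))
  expect_equal(unname(labelClusters(asg, c("A", "A", "A", "B", "C"))), "A")
  asg5 <- make_assignment(rep(0, 5))
  expect_equal(unname(labelClusters(asg5, c("A", "A", "B", "B", "C"))),
               "unannotated")
  asg4 <- make_assignment(rep(0, 4))
  expect_equal(unname(labelClusters(asg4, c("B", "B", "A", "A"))), "A")
  # missing labels count in the denominator but never label a cluster
  expect_equal(unname(labelClusters(asg4, c("A", "A", NA, NA))), "A")
  expect_equal(unname(labelClusters(asg4, c("A", NA, NA, NA))),
               "unannotated")
})

test_that("external scores are perfect on identical partitions and
           label-permutation invariant", {
  cl <- c(0, 0, 1, 1, 2, 2)
  asg <- make_assignment(cl)
  ref <- c("a", "a", "b", "b", "c", "c")
  sc <- externalScores(asg, ref)
  expect_equal(sc$ari, 1)
  expect_equal(sc$nmi, 1)
  expect_true(all(sc$per_type$f1 == 1))

  # trivial clustering of a 2-type reference: ARI exactly 0
  sc2 <- externalScores(make_assignment(rep(0, 4)), c("A", "A", "B", "B"))
  expect_equal(sc2$ari, 0)

  # renaming clusters changes nothing
  perm <- c(1, 2, 0)
  sc3 <- externalScores(make_assignment(perm[cl + 1]), ref)
  expect_equal(sc3$ari, sc$ari)
  expect_equal(sc3$nmi, sc$nmi)
  expect_equal(sc3$per_type, sc$per_type)
})

test_that("ARI and NMI equal independent oracles and external references", {
  set.seed(17)
  for (r in 1:20) {
    n <- sample(10:40, 1)
    a <- sample(0:3, n, replace = TRUE)
    b <- sample(letters[1:3], n, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), oracle_ari(a, b),
                 tolerance = 1e-9)
    expect_equal(normalizedMutualInfo(a, b), oracle_nmi(a, b),
                 tolerance = 1e-9)
  }
  skip_if_not_installed("mclust")
  set.seed(18)
  a <- sample(0:4, 100, replace = TRUE); b <- sample(0:3, 100, replace = TRUE)
  expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("ARI of independent random partitions is centered at zero", {
  set.seed(19)
  vals <- vapply(1:200, function(i)
    adjustedRandIndex(sample(0:4, 100, replace = TRUE),
                      sample(0:3, 100, replace = TRUE)), 0)
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("the full evaluation report carries ranges and conventions", {
  set.seed(20)
  x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 6), 20, 2))
  asg <- make_assignment(rep(0:1, each = 20))
  ln <- matrix(rpois(2 * 40, 1), 2,
               dimnames = list(c("g1", "g2"), sprintf("c%02d", 1:40)))
  rep <- evaluateEmbedding(x, asg, sce = ln, goi_genes = c("g1", "g2"),
                           labels = rep(c("t1", "t2"), each = 20))
  s <- reportScores(rep)
  expect_gte(s$asw, -1); expect_lte(s$asw, 1)
  expect_gte(s$nmi, 0); expect_lte(s$nmi, 1)
  expect_gte(s$distinctiveness, 0); expect_lte(s$distinctiveness, 1)
  expect_gte(s$dbi, 0); expect_gte(s$chi, 0)
  expect_equal(s$ari, 1)
})

test_that("the rank-sum marker utility flags an obvious marker", {
  set.seed(21)
  ln <- rbind(mk = c(rnorm(20, 3), rnorm(20, 0.2)),
              bg = rnorm(40))
  colnames(ln) <- sprintf("c%02d", 1:40)
  asg <- make_assignment(rep(0:1, each = 20))
  res <- rankSumTest(ln, asg, "mk", 0)
  expect_lt(res$p_value, 1e-5)
  expect_gt(res$log_fc, 1)
})
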