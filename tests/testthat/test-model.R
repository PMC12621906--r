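test_that("GOI target construction handles identity, sum and min-signature-z", {
  ln <- rbind(CD8A = c(1, 3, 0), CD8B = c(2, 0, 1), X = c(5, 5, 5))
  sce <- tiny_sce(exp(ln) - 1 + 1e-12, genes = rownames(ln))  # counts dummy
  SummarizedExperiment::assay(sce, "lognorm", withDimnames = FALSE) <- ln

  spec <- goiSpec("CD8A",
                  list(name = "CD8", kind = "sum", genes = c("CD8A", "CD8B")))
  y <- buildGoiTargets(sce, spec)
  expect_equal(unname(y[, "CD8A"]), c(1, 3, 0))
  expect_equal(unname(y[, "CD8"]), c(3, 3, 1))

  # min over two z-scored signature averages: hand-checkable 3-cell case
  ln2 <- rbind(s1a = c(0, 1, 2), s1b = c(0, 1, 2),
               s2a = c(2, 1, 0), s2b = c(4, 1, -2))
  sce2 <- tiny_sce(abs(ln2), genes = rownames(ln2))
  SummarizedExperiment::assay(sce2, "lognorm", withDimnames = FALSE) <- ln2
  mz <- goiSpec(list(name = "sen", kind = "min_signature_z",
                     genes = character(),
                     signatures = list(up = c("s1a", "s1b"),
                                       dn = c("s2a", "s2b"))))
  y2 <- buildGoiTargets(sce2, mz)
  z <- c(-1, 0, 1) * sqrt(3 / 2)  # population z-score of (0,1,2)
  expect_equal(unname(y2[, 1]), pmin(z, -z))

  expect_error(buildGoiTargets(sce, goiSpec(genes = "ABSENT")), "absent")
  const <- goiSpec(list(name = "k", kind = "min_signature_z",
                        genes = character(),
                        signatures = list(flat = "X")))
  expect_error(buildGoiTargets(sce, const), "constant")
})

test_that("GOI specifications validate and round-trip through the file format", {
  expect_error(goiSpec(list(name = "a", kind = "nope", genes = "g")),
               "unknown target kind")
  expect_error(goiSpec("A", "A"), "unique")

  spec <- goiSpec("CD8A",
                  list(name = "CD8", kind = "sum", genes = c("CD8A", "CD8B")),
                  list(name = "SEN", kind = "min_signature_z",
                       genes = character(),
                       signatures = list(a = c("x", "y"), b = c("z"))))
  path <- tempfile(fileext = ".txt")
  writeGOISpec(spec, path)
  back <- readGOISpec(path)
  expect_equal(goiNames(back), goiNames(spec))
  expect_equal(back@targets[[2]]$genes, c("CD8A", "CD8B"))
  expect_equal(back@targets[[3]]$signatures[[1]], c("x", "y"))
})

test_that("forward pass respects the dataflow (head and decoder fed from the
           bottleneck) and is deterministic", {
  cfg <- sakuraConfig(hidden_widths = c(6, 5, 4), bottleneck_dim = 3,
                      goi_head_hidden = c(4, 4))
  m <- sakuraModel(8, goi = goiSpec(genes = c("a", "b")), config = cfg,
                   seed = 2)
  x <- matrix(rnorm(5 * 8), 5, 8)
  out <- sakuraForward(m, x)
  expect_equal(dim(out$embedding), c(5, 3))
  expect_equal(dim(out$reconstruction), c(5, 8))
  expect_equal(dim(out$goi_pred), c(5, 2))

  # identical input rows give identical outputs
  x2 <- x[c(1, 1, 3, 4, 5), ]
  out2 <- sakuraForward(m, x2)
  expect_equal(out2$reconstruction[1, ], out2$reconstruction[2, ])

  # zeroed final decoder layer: reconstruction equals its bias for any input
  m0 <- m
  last <- length(m0@params$dec)
  m0@params$dec[[last]]$W[] <- 0
  m0@params$dec[[last]]$b[] <- 7
  expect_true(all(sakuraForward(m0, x)$reconstruction == 7))

  # perturbing decoder parameters leaves embedding and GOI prediction alone
  mp <- m
  mp@params$dec[[1]]$W <- mp@params$dec[[1]]$W + 1
  outp <- sakuraForward(mp, x)
  expect_equal(outp$embedding, out$embedding)
  expect_equal(outp$goi_pred, out$goi_pred)
  expect_false(isTRUE(all.equal(outp$reconstruction, out$reconstruction)))

  expect_error(sakuraForward(m, x[, 1:5]), "columns")
})

test_that("identity-initialized linear model reconstructs its input exactly
           (wiring oracle)", {
  cfg <- sakuraConfig(hidden_widths = c(4, 4, 4), bottleneck_dim = 4,
                      activation = "identity")
  m <- sakuraModel(4, config = cfg, seed = 1)
  for (part in c("enc", "dec")) {
    for (i in seq_along(m@params[[part]])) {
      m@params[[part]][[i]]$W <- diag(4)
      m@params[[part]][[i]]$b[] <- 0
    }
  }
  x <- matrix(rnorm(12), 3, 4)
  out <- sakuraForward(m, x)
  expect_equal(out$reconstruction, x)
  expect_equal(out$embedding, x)
})

test_that("reconstruction loss combines L1 and squared-L2 terms as stated", {
  expect_equal(reconstructionLoss(diag(3), diag(3)), 0)
  expect_equal(reconstructionLoss(matrix(c(1, 2), 1), matrix(c(0, 2), 1),
                                  lambda1 = 1, lambda2 = 1), 2)
  x <- matrix(rnorm(10), 2); y <- matrix(rnorm(10), 2)
  expect_equal(reconstructionLoss(x, y, 2, 0),
               2 * reconstructionLoss(x, y, 1, 0))
  # permutation over cells leaves the loss unchanged
  perm <- c(2, 1)
  expect_equal(reconstructionLoss(x[perm, ], y[perm, ]),
               reconstructionLoss(x, y))
})

test_that("GOI loss handles the cosine term per cell with the epsilon guard", {
  y <- matrix(c(1, 0), 1); yh <- matrix(c(0, 1), 1)
  expect_equal(goiLoss(y, y, 1, 1, 1), 0, tolerance = 1e-7)
  # orthogonal vectors: L1 term 2, cosine term 1
  expect_equal(goiLoss(y, yh, lambda4 = 1, lambda5 = 0, lambda6 = 1), 3,
               tolerance = 1e-6)
  expect_equal(goiLoss(y, yh, 0, 0, 0), 0)
  # both-zero rows contribute nothing to the cosine term
  expect_equal(goiLoss(matrix(0, 2, 3), matrix(0, 2, 3), 0, 0, 5), 0)
  # cosine term invariant to joint positive rescaling (lambda4 = lambda5 = 0)
  a <- matrix(rnorm(12), 3); b <- matrix(rnorm(12), 3)
  expect_equal(goiLoss(a, b, 0, 0, 1), goiLoss(3 * a, 5 * b, 0, 0, 1),
               tolerance = 1e-6)
  # permutation invariance over cells
  perm <- c(3, 1, 2)
  expect_equal(goiLoss(a[perm, ], b[perm, ]), goiLoss(a, b))
})

test_that("total loss is the plain sum of its components", {
  expect_equal(totalLoss(2, 0, 3), 5)
  expect_equal(totalLoss(0, 0, 0), 0)
})

test_that("analytic gradients match finite differences", {
  set.seed(31)
  cfg <- sakuraConfig(hidden_widths = c(4, 3, 3), bottleneck_dim = 2,
                      goi_head_hidden = c(3, 3))
  m <- sakuraModel(6, goi = goiSpec(genes = c("a", "b")), config = cfg,
                   seed = 5)
  x <- matrix(rnorm(5 * 6), 5, 6)
  y <- matrix(rnorm(5 * 2), 5, 2)
  act <- sakura:::act_fun("celu")
  p <- m@params
  loss_fn <- function(p) {
    enc <- sakura:::stack_forward(p$enc, x, act)
    dec <- sakura:::stack_forward(p$dec, enc$out, act)
    head <- sakura:::stack_forward(p$goi, enc$out, act)
    reconstructionLoss(x, dec$out, 1, 1) +
      goiLoss(y, head$out, 0.7, 0.5, 0.9)
  }
  enc <- sakura:::stack_forward(p$enc, x, act)
  dec <- sakura:::stack_forward(p$dec, enc$out, act)
  head <- sakura:::stack_forward(p$goi, enc$out, act)
  d <- x - dec$out
  bw_dec <- sakura:::stack_backward(p$dec, dec, -sign(d) - 2 * d, act)
  dyp <- sakura:::goi_loss_grad(y, head$out, 0.7, 0.5, 0.9)
  bw_head <- sakura:::stack_backward(p$goi, head, dyp, act)
  bw_enc <- sakura:::stack_backward(p$enc, enc, bw_dec$dx + bw_head$dx, act,
                                    need_dx = FALSE)
  eps <- 1e-6
  worst <- 0
  for (part in c("enc", "dec", "goi")) {
    bw <- switch(part, enc = bw_enc, dec = bw_dec, goi = bw_head)
    for (li in seq_along(p[[part]])) for (what in c("W", "b")) {
      g <- bw$grads[[li]][[what]]
      for (idx in sample(length(g), min(3, length(g)))) {
        pp <- p; pp[[part]][[li]][[what]][idx] <- pp[[part]][[li]][[what]][idx] + eps
        pm <- p; pm[[part]][[li]][[what]][idx] <- pm[[part]][[li]][[what]][idx] - eps
        ng <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        worst <- max(worst, abs(g[idx] - ng) /
                       max(1e-8, abs(ng) + abs(g[idx])))
      }
    }
  }
  expect_lt(worst, 1e-5)
})
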