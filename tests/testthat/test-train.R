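test_that("the train/test split is a reproducible partition with the floor
           convention", {
  s <- splitCells(10, 0.5, seed = 3)
  expect_length(s$train, 5)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(s, splitCells(10, 0.5, seed = 3))
  expect_false(identical(s$train, splitCells(10, 0.5, seed = 4)$train))

  s7 <- splitCells(7, 0.5, seed = 1)
  expect_length(s7$train, 3)
  expect_length(s7$test, 4)
  expect_error(splitCells(1, 0.5), "at least 2")
})

test_that("lambda ramp schedules follow the stated laws over all epochs", {
  cfg <- trainConfig()
  expect_equal(lambdaSchedule(0, "l3", cfg), 1e-4)
  expect_equal(lambdaSchedule(49, "goi", cfg), 0)
  expect_equal(lambdaSchedule(50, "goi", cfg), 0.01)
  expect_equal(lambdaSchedule(149, "goi", cfg), 1)  # cap after 100 increments
  expect_equal(lambdaSchedule(148, "goi", cfg), 0.99)

  l3 <- vapply(0:299, lambdaSchedule, 0, which = "l3", config = cfg)
  lg <- vapply(0:299, lambdaSchedule, 0, which = "goi", config = cfg)
  expect_true(all(diff(l3) >= 0) && all(l3 <= 1))
  expect_true(all(diff(lg) >= 0) && all(lg <= 1))
  expect_true(all(lg[1:50] == 0))

  mult <- trainConfig(schedule_l3 = list(init = 1e-4, increment = 0.01,
                                         cap = 1, multiplicative = TRUE))
  expect_equal(lambdaSchedule(10, "l3", mult), 1e-4 * 1.01^10)

  strong <- trainConfig(goi_multiplier = 1000)
  expect_equal(lambdaSchedule(149, "goi", strong), 1000)
})

test_that("with all supervision off the trajectory equals an independently
           written plain autoencoder", {
  sim <- small_sim(n_cells = 120, n_genes = 40, seed = 5)
  sce <- scaleGenes(logNormalize(sim$sce))
  x <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled")))
  mc <- sakuraConfig(hidden_widths = c(12, 10, 8), bottleneck_dim = 5)
  tc <- trainConfig(epochs = 10L, batch_rec = 32L, include_reg = FALSE,
                    schedule_goi = list(start_epoch = 5L, increment = 0.01,
                                        cap = 1), seed = 17)
  m1 <- trainSakura(x, NULL, model_config = mc, config = tc)
  m2 <- sakura:::train_plain_ae(x, model_config = mc, config = tc)
  expect_identical(m1@params$enc, m2@params$enc)
  expect_identical(m1@params$dec, m2@params$dec)
  expect_equal(m1@history$rec_train, m2@history$rec_train)
})

test_that("training is seed-deterministic and its reconstruction loss
           decreases early", {
  sim <- small_sim(n_cells = 150, n_genes = 40, seed = 6)
  sce <- scaleGenes(logNormalize(sim$sce))
  x <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled")))
  tc <- trainConfig(epochs = 12L, batch_rec = 50L, batch_goi = 25L,
                    schedule_goi = list(start_epoch = 4L, increment = 0.05,
                                        cap = 1), seed = 23)
  mc <- sakuraConfig(hidden_widths = c(16, 12, 10), bottleneck_dim = 6)
  y <- buildGoiTargets(sce, goiSpec(genes = sim$markers[1:2]))
  m1 <- trainSakura(x, y, model_config = mc, config = tc)
  m2 <- trainSakura(x, y, model_config = mc, config = tc)
  expect_identical(m1@history, m2@history)

  drops <- vapply(1:3, function(s) {
    tc$seed <- s
    m <- trainSakura(x, NULL, model_config = mc, config = tc)
    m@history$rec_train[1] - m@history$rec_train[10]
  }, 0)
  expect_gt(median(drops), 0)
})

test_that("the canary flags a displaced test cloud and passes a copied one", {
  sim <- small_sim(n_cells = 100, n_genes = 30, seed = 2)
  sce <- scaleGenes(logNormalize(sim$sce))
  x <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled")))
  tc <- trainConfig(epochs = 4L, batch_rec = 32L, include_reg = FALSE,
                    schedule_goi = list(start_epoch = 2L, increment = 0.01,
                                        cap = 1), seed = 5)
  mc <- sakuraConfig(hidden_widths = c(12, 10, 8), bottleneck_dim = 5)
  m <- trainSakura(x, NULL, model_config = mc, config = tc)
  emb <- embedCells(m, x)
  tr <- emb[m@config$split$train, ]
  # force equal train/test losses for the copied-cloud check
  m@history$rec_test[nrow(m@history)] <-
    m@history$rec_train[nrow(m@history)]
  same <- canaryCheck(m, tr, tr, n_slices = 20, seed = 1)
  expect_false(same$flag)
  expect_equal(same$loss_gap, 0)
  shifted <- canaryCheck(m, tr, tr + 50, n_slices = 20, seed = 1)
  expect_true(shifted$flag)
})

test_that("the regularization decision rule prefers the cluster count closer
           to the baseline, with ties kept regularized", {
  expect_equal(regDecisionRule(10, 9, 6), "with")
  expect_equal(regDecisionRule(8, 12, 8), "without")
  expect_equal(regDecisionRule(10, 12, 8), "with")  # tie
})

test_that("decideRegularization trains both variants and honors its own rule", {
  sim <- small_sim(n_cells = 200, n_genes = 50, seed = 9)
  sce <- preprocess(sim$sce, n_genes = 50, n_pcs = 20)
  x <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled")))
  y <- buildGoiTargets(sce, goiSpec(genes = sim$markers[1:2]))
  pca <- SingleCellExperiment::reducedDim(sce, "PCA")
  tc <- trainConfig(epochs = 8L, batch_rec = 64L, batch_goi = 32L,
                    schedule_goi = list(start_epoch = 3L, increment = 0.1,
                                        cap = 1), seed = 3)
  mc <- sakuraConfig(hidden_widths = c(16, 12, 10), bottleneck_dim = 8)
  dec <- decideRegularization(x, y, pca, model_config = mc, config = tc,
                              n_neighbors = 10)
  expect_true(dec$choice %in% c("with", "without"))
  expect_equal(dec$choice,
               regDecisionRule(dec$record["k_baseline"],
                               dec$record["k_with"],
                               dec$record["k_without"]))
  expect_s4_class(dec$model, "SakuraModel")
})

test_that("embedding all cells covers train and test alike and is
           input-deterministic", {
  sim <- small_sim(n_cells = 80, n_genes = 30, seed = 4)
  sce <- scaleGenes(logNormalize(sim$sce))
  x <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled")))
  tc <- trainConfig(epochs = 3L, batch_rec = 32L, include_reg = FALSE,
                    schedule_goi = list(start_epoch = 1L, increment = 0.01,
                                        cap = 1), seed = 6)
  mc <- sakuraConfig(hidden_widths = c(12, 10, 8), bottleneck_dim = 5)
  m <- trainSakura(x, NULL, model_config = mc, config = tc)
  emb <- embedCells(m, x)
  expect_equal(nrow(emb), nrow(x))
  x2 <- rbind(x, x[7, , drop = FALSE])
  emb2 <- embedCells(m, x2)
  expect_equal(unname(emb2[nrow(x2), ]), unname(emb[7, ]))
})

test_that("model checkpoints round-trip with their schema id", {
  cfg <- sakuraConfig(hidden_widths = c(8, 6, 5), bottleneck_dim = 3)
  m <- sakuraModel(10, goi = goiSpec(genes = c("a", "b")), config = cfg,
                   seed = 4)
  path <- tempfile(fileext = ".rds")
  saveSakuraModel(m, path)
  back <- readSakuraModel(path)
  expect_identical(back@params, m@params)
  expect_identical(back@config, m@config)
  x <- matrix(rnorm(30), 3, 10)
  expect_identical(sakuraForward(back, x), sakuraForward(m, x))
  # corrupted schema rejected
  saveRDS(list(schema = "other"), path)
  expect_error(readSakuraModel(path), "schema")
})
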