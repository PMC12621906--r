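#' End-to-end knowledge-guided embedding run
#'
#' Convenience wrapper over the full pipeline: preprocess (log-normalize,
#' highly variable genes, scale, PCA baseline), build the
#' genes-of-interest targets, train the knowledge-guided autoencoder
#' (optionally deciding on the regularization component by the
#' cluster-count rule), embed all cells, cluster the embedding, and
#' evaluate.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with assay
#'   \code{"counts"}.
#' @param goi a [GOISpec-class], or NULL for an unsupervised run.
#' @param n_hvg number of highly variable genes (genes of interest are
#'   force-included by default).
#' @param force_include_goi keep GOI genes in the variable set even when
#'   below the variance cutoff.
#' @param scale_factor library-size scale factor.
#' @param n_pcs PCA baseline dimensions.
#' @param model_config,train_config architecture and training settings.
#' @param auto_reg decide the regularization component by comparing
#'   cluster counts against the PCA baseline (doubles the training cost);
#'   when FALSE the \code{train_config$include_reg} setting is used as
#'   is.
#' @param n_neighbors,resolution clustering settings.
#' @param labels optional reference labels for external validation.
#' @param seed run seed (overrides \code{train_config$seed}).
#' @return list with \code{sce} (carrying reducedDims \code{"PCA"} and
#'   \code{"SAKURA"}), \code{model}, \code{clusters},
#'   \code{clusters_pca}, \code{report}, \code{report_pca},
#'   \code{canary}, and \code{reg_decision} when \code{auto_reg}
#' @export
runPipeline <- function(sce, goi = NULL, n_hvg = min(nrow(sce), 1e4),
                        force_include_goi = TRUE, scale_factor = 1e4,
                        n_pcs = 50,
                        model_config = sakuraConfig(),
                        train_config = trainConfig(),
                        auto_reg = FALSE, n_neighbors = 20,
                        resolution = 0.8, labels = NULL, seed = NULL) {
  if (!is.null(seed)) train_config$seed <- seed
  seed <- train_config$seed
  force <- if (!is.null(goi) && force_include_goi) goiGenes(goi)
  sce <- preprocess(sce, scale_factor = scale_factor, n_genes = n_hvg,
                    force_include = force %||% character(), n_pcs = n_pcs)
  x <- t(SummarizedExperiment::assay(sce, "scaled"))
  targets <- if (!is.null(goi)) buildGoiTargets(sce, goi)
  pca <- SingleCellExperiment::reducedDim(sce, "PCA")

  reg_decision <- NULL
  if (auto_reg) {
    reg_decision <- decideRegularization(
      x, targets, pca, model_config = model_config, config = train_config,
      n_neighbors = n_neighbors, resolution = resolution)
    model <- reg_decision$model
  } else {
    model <- trainSakura(x, targets, goi = goi,
                         model_config = model_config, config = train_config)
  }
  emb <- embedCells(model, x)
  SingleCellExperiment::reducedDim(sce, "SAKURA") <- emb
  clusters <- snnCluster(emb, n_neighbors, resolution, seed = seed)
  clusters_pca <- snnCluster(pca, n_neighbors, resolution, seed = seed)
  goi_genes <- if (!is.null(goi)) intersect(goiGenes(goi), rownames(sce))
  report <- evaluateEmbedding(emb, clusters, sce = sce,
                              goi_genes = goi_genes, labels = labels)
  report_pca <- evaluateEmbedding(pca, clusters_pca, sce = sce,
                                  goi_genes = goi_genes, labels = labels)
  split <- model@config$split
  canary <- canaryCheck(model, emb[split$train, , drop = FALSE],
                        emb[split$test, , drop = FALSE], seed = seed)
  list(sce = sce, model = model, clusters = clusters,
       clusters_pca = clusters_pca, report = report,
       report_pca = report_pca, canary = canary,
       reg_decision = reg_decision)
}

#' Write the artifacts of a pipeline run
#'
#' Plain-text mirrors of every artifact: the embeddings (CSV), cluster
#' assignments (TSV), evaluation reports (JSON) and the training history
#' (TSV).
#'
#' @param run result of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly
#' @export
writeRun <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEmbedding(SingleCellExperiment::reducedDim(run$sce, "SAKURA"),
                 file.path(dir, "embedding.csv"))
  writeEmbedding(SingleCellExperiment::reducedDim(run$sce, "PCA"),
                 file.path(dir, "embedding_pca.csv"))
  writeClusters(run$clusters, file.path(dir, "clusters.tsv"))
  writeClusters(run$clusters_pca, file.path(dir, "clusters_pca.tsv"))
  for (nm in c("report", "report_pca")) {
    jsonlite::write_json(reportScores(run[[nm]]),
                         file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  write.table(run$model@history, file.path(dir, "train_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # resolved-config snapshot so the run is reproducible from the artifacts
  cfg <- run$model@config
  snap <- list(model = cfg[setdiff(names(cfg),
                                   c("split", "train_config"))],
               train = cfg$train_config,
               canary = run$canary[c("loss_gap", "sw2", "sw2_baseline",
                                     "flag")],
               reg_decision = run$reg_decision$record)
  jsonlite::write_json(snap, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
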