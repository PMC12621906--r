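#' Training configuration
#'
#' Defaults follow the published training recipe: RMSProp (lr 0.001,
#' smoothing 0.9), a 50/50 train/test split, reconstruction +
#' regularization updates in batches of 200 cells followed by
#' knowledge-head updates in batches of 100 cells, \code{lambda3} ramped
#' additively from 1e-4 by 0.01 per epoch (cap 1), and
#' \code{lambda4..lambda6} held at 0 for the first 50 epochs then ramped by
#' 0.01 per epoch (cap 1), so that the model captures general structure
#' first and attends to the genes of interest progressively.
#'
#' @param epochs maximum epochs (default 300).
#' @param batch_rec,batch_goi batch sizes of the two passes.
#' @param lr,alpha RMSProp learning rate and smoothing.
#' @param split_fraction training fraction of cells.
#' @param include_reg include the sliced-Wasserstein regularization.
#' @param reg_k,reg_n_slices,reg_squared uniform-prior half width, number
#'   of slices, and whether the squared distance is used.
#' @param schedule_l3 list(init, increment, cap, multiplicative): the
#'   \code{lambda3} ramp. \code{multiplicative = TRUE} switches the
#'   "1 percent per epoch" reading to a geometric ramp.
#' @param schedule_goi list(start_epoch, increment, cap): the
#'   \code{lambda4..6} ramp; \code{start_epoch} counts completed epochs
#'   before the first nonzero value (50 means the first 50 epochs are
#'   unsupervised).
#' @param goi_multiplier supervision-intensity multiplier applied to the
#'   whole \code{lambda4..6} schedule (caps included).
#' @param lambda4_on,lambda5_on,lambda6_on include each GOI loss term.
#' @param early_stop_tol,early_stop_patience stop when the total training
#'   loss improves relatively by less than the tolerance for this many
#'   consecutive epochs (only active once all ramps have reached their
#'   caps).
#' @param seed run seed; every shuffle, prior draw and slice draw derives
#'   from it.
#' @return a named list of settings
#' @export
trainConfig <- function(epochs = 300L, batch_rec = 200L, batch_goi = 100L,
                        lr = 0.001, alpha = 0.9, split_fraction = 0.5,
                        include_reg = TRUE, reg_k = 5, reg_n_slices = 50L,
                        reg_squared = FALSE,
                        schedule_l3 = list(init = 1e-4, increment = 0.01,
                                           cap = 1, multiplicative = FALSE),
                        schedule_goi = list(start_epoch = 50L,
                                            increment = 0.01, cap = 1),
                        goi_multiplier = 1,
                        lambda4_on = TRUE, lambda5_on = TRUE,
                        lambda6_on = TRUE,
                        early_stop_tol = 1e-5, early_stop_patience = 20L,
                        seed = 1L) {
  stopifnot(epochs >= 1, batch_rec >= 1, batch_goi >= 1,
            split_fraction > 0, split_fraction < 1,
            schedule_l3$cap >= schedule_l3$init, schedule_l3$init >= 0,
            schedule_goi$cap >= 0, schedule_goi$start_epoch < epochs)
  as.list(environment())
}

#' Random train/test split of cells
#'
#' Disjoint, exhaustive, reproducible under the seed; the training set has
#' \code{floor(fraction * M)} cells.
#'
#' @param M number of cells (>= 2).
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer vectors \code{train} and \code{test}
#' @export
splitCells <- function(M, fraction = 0.5, seed = 1L) {
  if (M < 2) stopf("need at least 2 cells to split")
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0,1)")
  n_train <- floor(fraction * M)
  train <- with_seed(derive_seed(seed, "split"),
                     sort(sample.int(M, n_train)))
  list(train = train, test = setdiff(seq_len(M), train))
}

#' Loss-weight ramp schedules
#'
#' \code{lambdaSchedule(epoch, "l3", cfg)} gives the regularization weight
#' at a 0-based epoch: \code{min(cap, init + increment * epoch)} (or
#' \code{init * (1 + increment)^epoch} in multiplicative mode).
#' \code{lambdaSchedule(epoch, "goi", cfg)} gives the common
#' \code{lambda4..6} base value: 0 while \code{epoch < start_epoch}, then
#' \code{min(cap, increment * (epoch - start_epoch + 1))}, times the
#' supervision-intensity multiplier.
#'
#' @param epoch 0-based epoch index.
#' @param which \code{"l3"} or \code{"goi"}.
#' @param config list from [trainConfig()].
#' @return the weight value at that epoch
#' @export
lambdaSchedule <- function(epoch, which = c("l3", "goi"),
                           config = trainConfig()) {
  which <- match.arg(which)
  stopifnot(epoch >= 0)
  if (which == "l3") {
    s <- config$schedule_l3
    if (isTRUE(s$multiplicative))
      return(min(s$cap, s$init * (1 + s$increment)^epoch))
    return(min(s$cap, s$init + s$increment * epoch))
  }
  s <- config$schedule_goi
  if (epoch < s$start_epoch) return(0)
  config$goi_multiplier * min(s$cap, s$increment * (epoch - s$start_epoch + 1))
}

make_batches <- function(ids, batch_size, seed) {
  shuffled <- with_seed(seed, sample(ids))
  split(shuffled, ceiling(seq_along(shuffled) / batch_size))
}

#' Train a SAKURA model
#'
#' Alternating batched training: in every epoch, one pass of
#' reconstruction + regularization updates over the training cells
#' (encoder and decoder), then one pass of genes-of-interest regression
#' updates (encoder and head; decoder frozen). Per-epoch loss components
#' on the training and held-out testing cells are recorded in the model
#' history; losses are reported per cell so that values are comparable
#' across batch and split sizes. Training is deterministic given the seed.
#'
#' @param x cells x genes matrix of scaled expression values (model
#'   input).
#' @param goi_targets cells x targets matrix from [buildGoiTargets()], or
#'   \code{NULL} for an unsupervised run.
#' @param goi optional [GOISpec-class] stored with the model.
#' @param model_config list from [sakuraConfig()].
#' @param config list from [trainConfig()].
#' @param verbose print a line every 25 epochs.
#' @return a trained [SakuraModel-class]; the split used is stored in
#'   \code{model@config$split}
#' @export
trainSakura <- function(x, goi_targets = NULL, goi = NULL,
                        model_config = sakuraConfig(),
                        config = trainConfig(), verbose = FALSE) {
  x <- as.matrix(x)
  M <- nrow(x)
  seed <- config$seed
  if (!is.null(goi_targets)) {
    goi_targets <- as.matrix(goi_targets)
    if (nrow(goi_targets) != M) stopf("goi_targets rows must match cells")
    if (is.null(goi))
      goi <- goiSpec(genes = colnames(goi_targets) %||%
                       paste0("target", seq_len(ncol(goi_targets))))
  }
  model <- sakuraModel(ncol(x), goi = goi, config = model_config, seed = seed)
  act <- act_fun(model@config$activation)
  l1 <- model@config$lambda1; l2 <- model@config$lambda2
  split <- splitCells(M, config$split_fraction, seed)
  tr <- split$train; te <- split$test
  prior <- priorSpec(k = config$reg_k, dims = model@config$bottleneck_dim)

  p <- model@params
  # One optimizer per optimization pass; the encoder keeps separate RMSProp
  # state for the reconstruction pass and the GOI pass. Because RMSProp
  # normalizes per-parameter gradient scale, the ramped lambda4..6 value
  # enters the GOI pass as a learning-rate factor on the normalized update
  # (gradients are computed with the unit term mix): this keeps the
  # supervision intensity meaningful independent of the gene-count scale
  # of the reconstruction loss, and lets extreme intensities over-drive
  # the encoder, which is the over-supervision regime the silhouette sign
  # is meant to flag.
  st <- list(enc = rmsprop_state(p$enc), dec = rmsprop_state(p$dec),
             enc_goi = rmsprop_state(p$enc),
             goi = if (!is.null(p$goi)) rmsprop_state(p$goi))
  hist <- vector("list", config$epochs)
  best <- Inf; stall <- 0L
  caps_done_at <- max(
    if (config$include_reg && config$schedule_l3$increment > 0)
      ceiling((config$schedule_l3$cap - config$schedule_l3$init) /
                config$schedule_l3$increment) else 0,
    if (!is.null(goi_targets) && config$schedule_goi$increment > 0)
      config$schedule_goi$start_epoch +
        ceiling(config$schedule_goi$cap / config$schedule_goi$increment)
    else 0)

  for (e in seq_len(config$epochs) - 1L) {
    l3 <- if (config$include_reg) lambdaSchedule(e, "l3", config) else 0
    lg <- lambdaSchedule(e, "goi", config)
    l4 <- if (config$lambda4_on) lg else 0
    l5 <- if (config$lambda5_on) lg else 0
    l6 <- if (config$lambda6_on) lg else 0

    # --- reconstruction + regularization pass (encoder + decoder) ---
    rec_sum <- 0; reg_sum <- 0; n_b <- 0L
    batches <- make_batches(tr, config$batch_rec,
                            derive_seed(seed, "rec-shuffle", e))
    for (bi in seq_along(batches)) {
      xb <- x[batches[[bi]], , drop = FALSE]
      B <- nrow(xb)
      enc <- stack_forward(p$enc, xb, act)
      dec <- stack_forward(p$dec, enc$out, act)
      d <- xb - dec$out
      rec_sum <- rec_sum + (l1 * sum(abs(d)) + l2 * sum(d^2)) / B
      dxp <- (-l1 * sign(d) - 2 * l2 * d) / B
      bw_dec <- stack_backward(p$dec, dec, dxp, act)
      dH <- bw_dec$dx
      if (l3 > 0) {
        P <- sample_prior(prior, B, derive_seed(seed, "prior", e, bi))
        sw <- sliced_w2_with_grad(enc$out, P, config$reg_n_slices,
                                  derive_seed(seed, "slices", e, bi))
        if (config$reg_squared) {
          reg_sum <- reg_sum + l3 * sw$value^2
          dH <- dH + l3 * 2 * sw$value * sw$grad
        } else {
          reg_sum <- reg_sum + l3 * sw$value
          dH <- dH + l3 * sw$grad
        }
      }
      bw_enc <- stack_backward(p$enc, enc, dH, act, need_dx = FALSE)
      up <- rmsprop_update(p$enc, bw_enc$grads, st$enc, config$lr,
                           config$alpha)
      p$enc <- up$layers; st$enc <- up$state
      up <- rmsprop_update(p$dec, bw_dec$grads, st$dec, config$lr,
                           config$alpha)
      p$dec <- up$layers; st$dec <- up$state
      n_b <- n_b + 1L
    }
    rec_tr <- rec_sum / n_b; reg_tr <- reg_sum / n_b

    # --- genes-of-interest pass (encoder + head; decoder frozen) ---
    goi_tr <- 0
    if (!is.null(goi_targets) && (l4 > 0 || l5 > 0 || l6 > 0)) {
      gsum <- 0; gb <- 0L
      # intensity = common ramp value; term mix enters the gradient with
      # unit weights, intensity scales the normalized update
      intensity <- max(l4, l5, l6)
      w4 <- l4 / intensity; w5 <- l5 / intensity; w6 <- l6 / intensity
      lr_goi <- config$lr * intensity
      batches <- make_batches(tr, config$batch_goi,
                              derive_seed(seed, "goi-shuffle", e))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        xb <- x[idx, , drop = FALSE]
        yb <- goi_targets[idx, , drop = FALSE]
        B <- nrow(xb)
        enc <- stack_forward(p$enc, xb, act)
        head <- stack_forward(p$goi, enc$out, act)
        gsum <- gsum + goiLoss(yb, head$out, l4, l5, l6) / B
        dyp <- goi_loss_grad(yb, head$out, w4, w5, w6) / B
        bw_head <- stack_backward(p$goi, head, dyp, act)
        bw_enc <- stack_backward(p$enc, enc, bw_head$dx, act,
                                 need_dx = FALSE)
        up <- rmsprop_update(p$goi, bw_head$grads, st$goi, lr_goi,
                             config$alpha)
        p$goi <- up$layers; st$goi <- up$state
        up <- rmsprop_update(p$enc, bw_enc$grads, st$enc_goi, lr_goi,
                             config$alpha)
        p$enc <- up$layers; st$enc_goi <- up$state
        gb <- gb + 1L
      }
      goi_tr <- gsum / gb
    }

    # --- held-out diagnostics ---
    te_losses <- eval_losses(p, act, x[te, , drop = FALSE],
                             if (!is.null(goi_targets))
                               goi_targets[te, , drop = FALSE],
                             l1, l2, l4, l5, l6)
    total_tr <- rec_tr + reg_tr + goi_tr
    hist[[e + 1L]] <- data.frame(
      epoch = e, lambda3 = l3, lambda4 = l4, lambda5 = l5, lambda6 = l6,
      rec_train = rec_tr, rec_test = te_losses$rec, reg = reg_tr,
      goi_train = goi_tr, goi_test = te_losses$goi, total_train = total_tr)
    if (!any(is.finite(total_tr)))
      stopf("non-finite training loss at epoch %d", e)
    if (verbose && e %% 25L == 0L)
      message(sprintf("epoch %d: rec %.4f reg %.4f goi %.4f",
                      e, rec_tr, reg_tr, goi_tr))
    if (e >= caps_done_at) {
      if (total_tr < best * (1 - config$early_stop_tol)) {
        best <- total_tr; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) {
          hist <- hist[seq_len(e + 1L)]
          break
        }
      }
    } else best <- min(best, total_tr)
  }

  model@params <- p
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model@config$split <- split
  model@config$train_config <- config
  methods::validObject(model)
  model
}

eval_losses <- function(p, act, x, y, l1, l2, l4, l5, l6) {
  enc <- stack_forward(p$enc, x, act)
  dec <- stack_forward(p$dec, enc$out, act)
  rec <- reconstructionLoss(x, dec$out, l1, l2) / nrow(x)
  g <- 0
  if (!is.null(y) && !is.null(p$goi) && (l4 > 0 || l5 > 0 || l6 > 0)) {
    head <- stack_forward(p$goi, enc$out, act)
    g <- goiLoss(y, head$out, l4, l5, l6) / nrow(x)
  }
  list(rec = rec, goi = g)
}

# Independent plain-autoencoder trainer used as a wiring oracle: same
# seed-derivation scheme, reconstruction pass only, written as a
# self-contained loop.
train_plain_ae <- function(x, model_config = sakuraConfig(),
                           config = trainConfig(include_reg = FALSE)) {
  x <- as.matrix(x)
  seed <- config$seed
  model <- sakuraModel(ncol(x), goi = NULL, config = model_config,
                       seed = seed)
  act <- act_fun(model@config$activation)
  l1 <- model@config$lambda1; l2 <- model@config$lambda2
  split <- splitCells(nrow(x), config$split_fraction, seed)
  p <- model@params
  st <- list(enc = rmsprop_state(p$enc), dec = rmsprop_state(p$dec))
  losses <- numeric(config$epochs)
  for (e in seq_len(config$epochs) - 1L) {
    rec_sum <- 0; n_b <- 0L
    for (idx in make_batches(split$train, config$batch_rec,
                             derive_seed(seed, "rec-shuffle", e))) {
      xb <- x[idx, , drop = FALSE]
      enc <- stack_forward(p$enc, xb, act)
      dec <- stack_forward(p$dec, enc$out, act)
      d <- xb - dec$out
      rec_sum <- rec_sum + (l1 * sum(abs(d)) + l2 * sum(d^2)) / nrow(xb)
      dxp <- (-l1 * sign(d) - 2 * l2 * d) / nrow(xb)
      bw_dec <- stack_backward(p$dec, dec, dxp, act)
      bw_enc <- stack_backward(p$enc, enc, bw_dec$dx, act, need_dx = FALSE)
      up <- rmsprop_update(p$enc, bw_enc$grads, st$enc, config$lr,
                           config$alpha)
      p$enc <- up$layers; st$enc <- up$state
      up <- rmsprop_update(p$dec, bw_dec$grads, st$dec, config$lr,
                           config$alpha)
      p$dec <- up$layers; st$dec <- up$state
      n_b <- n_b + 1L
    }
    losses[e + 1L] <- rec_sum / n_b
  }
  model@params <- p
  model@history <- data.frame(epoch = seq_len(config$epochs) - 1L,
                              rec_train = losses)
  model@config$split <- split
  model
}

#' Embed all cells
#'
#' Applies the trained encoder to every cell, training and testing alike.
#'
#' @param model a trained [SakuraModel-class].
#' @param x cells x genes matrix of scaled values (or a container with a
#'   \code{"scaled"} assay).
#' @return cells x bottleneck_dim embedding matrix
#' @export
embedCells <- function(model, x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- t(as.matrix(.get_assay(x, "scaled", "embedCells")))
  act <- act_fun(model@config$activation)
  emb <- stack_forward(model@params$enc, as.matrix(x), act)$out
  rownames(emb) <- rownames(x)
  colnames(emb) <- paste0("SK", seq_len(ncol(emb)))
  emb
}

#' Canary diagnostics on the held-out split
#'
#' Two checks that the training process has not gone wrong: (a) the
#' relative gap between final training and testing total loss, and (b) the
#' sliced 2-Wasserstein distance between the training-cell and
#' testing-cell embedding clouds, compared with a self-distance baseline
#' obtained by resampling halves of the training cloud. Flags when the
#' loss gap exceeds 0.5 or the cloud distance exceeds 3x the baseline.
#'
#' @param model a trained [SakuraModel-class] (for the loss history).
#' @param train_embedding,test_embedding embeddings of the two splits from
#'   the same encoder.
#' @param n_slices,seed sliced-distance settings.
#' @return list with \code{loss_gap}, \code{sw2}, \code{sw2_baseline},
#'   \code{flag}
#' @export
canaryCheck <- function(model, train_embedding, test_embedding,
                        n_slices = 50, seed = 1L) {
  h <- model@history
  last <- h[nrow(h), ]
  tr_loss <- last$rec_train + (last$goi_train %||% 0)
  te_loss <- last$rec_test + (last$goi_test %||% 0)
  gap <- abs(tr_loss - te_loss) / max(abs(tr_loss), 1e-12)
  A <- as.matrix(train_embedding); B <- as.matrix(test_embedding)
  n <- min(nrow(A), nrow(B))
  sub_a <- with_seed(derive_seed(seed, "canary-a"), sample(nrow(A), n))
  sub_b <- with_seed(derive_seed(seed, "canary-b"), sample(nrow(B), n))
  sw2 <- slicedW2(A[sub_a, , drop = FALSE], B[sub_b, , drop = FALSE],
                  n_slices, derive_seed(seed, "canary-sw"))
  base <- vapply(1:3, function(r) {
    half <- with_seed(derive_seed(seed, "canary-base", r),
                      sample(nrow(A), floor(nrow(A) / 2)))
    m <- min(length(half), nrow(A) - length(half))
    slicedW2(A[half[seq_len(m)], , drop = FALSE],
             A[-half, , drop = FALSE][seq_len(m), , drop = FALSE],
             n_slices, derive_seed(seed, "canary-sw", r))
  }, 0)
  baseline <- mean(base)
  list(loss_gap = gap, sw2 = sw2, sw2_baseline = baseline,
       flag = gap > 0.5 || sw2 > 3 * baseline)
}

#' Regularization decision rule
#'
#' The regularization component is included if and only if the number of
#' clusters it produces is at least as close to the unsupervised PCA
#' baseline's cluster count as the unregularized run's; ties prefer
#' regularization.
#'
#' @param k_baseline,k_with,k_without cluster counts from the PCA baseline
#'   and from the runs with and without regularization.
#' @return \code{"with"} or \code{"without"}
#' @export
regDecisionRule <- function(k_baseline, k_with, k_without) {
  if (abs(k_with - k_baseline) <= abs(k_without - k_baseline))
    "with" else "without"
}

#' Decide whether to include the regularization component
#'
#' Trains the model with and without the sliced-Wasserstein
#' regularization, clusters each embedding and the PCA baseline embedding
#' with identical settings, and keeps the variant whose cluster count is
#' closer to the baseline's (ties prefer regularization).
#'
#' @param x cells x genes scaled matrix.
#' @param goi_targets targets matrix or NULL.
#' @param pca_embedding cells x d PCA baseline embedding.
#' @param model_config,config as in [trainSakura()].
#' @param n_neighbors,resolution clustering settings applied to all three
#'   embeddings.
#' @return list with \code{model}, \code{choice} ("with"/"without"), and a
#'   \code{record} of the three cluster counts
#' @export
decideRegularization <- function(x, goi_targets, pca_embedding,
                                 model_config = sakuraConfig(),
                                 config = trainConfig(),
                                 n_neighbors = 20, resolution = 0.8) {
  config_with <- config; config_with$include_reg <- TRUE
  config_wo <- config; config_wo$include_reg <- FALSE
  m_with <- trainSakura(x, goi_targets, model_config = model_config,
                        config = config_with)
  m_wo <- trainSakura(x, goi_targets, model_config = model_config,
                      config = config_wo)
  seed <- config$seed
  k_base <- nClusters(snnCluster(pca_embedding, n_neighbors, resolution,
                                 seed = seed))
  k_with <- nClusters(snnCluster(embedCells(m_with, x), n_neighbors,
                                 resolution, seed = seed))
  k_wo <- nClusters(snnCluster(embedCells(m_wo, x), n_neighbors,
                               resolution, seed = seed))
  choice <- regDecisionRule(k_base, k_with, k_wo)
  list(model = if (choice == "with") m_with else m_wo, choice = choice,
       record = c(k_baseline = k_base, k_with = k_with, k_without = k_wo))
}
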