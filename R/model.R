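#' Architecture and loss configuration
#'
#' Defaults follow the published setup: three hidden layers of 100 nodes on
#' each side of a 50-node bottleneck, CELU activations (alpha = 1), a
#' two-hidden-layer (50/50) regression head on the bottleneck, and loss
#' weights \code{lambda1 = lambda2 = 1} for the L1/L2 reconstruction terms.
#'
#' @param input_dim number of input genes (set when the model is built if
#'   \code{NULL}).
#' @param hidden_widths integer vector of the three hidden-layer widths
#'   used by both encoder and decoder.
#' @param bottleneck_dim embedding dimensionality (default 50).
#' @param goi_head_hidden widths of the regression head's hidden layers.
#' @param activation \code{"celu"} (default) or \code{"identity"} (linear
#'   harness mode used by wiring tests).
#' @param lambda1,lambda2 reconstruction L1/L2 weights.
#' @param lambda6_cosine include the cosine term in the GOI loss.
#' @return a named list of settings
#' @export
sakuraConfig <- function(input_dim = NULL, hidden_widths = c(100, 100, 100),
                         bottleneck_dim = 50, goi_head_hidden = c(50, 50),
                         activation = "celu", lambda1 = 1, lambda2 = 1,
                         lambda6_cosine = TRUE) {
  stopifnot(all(hidden_widths >= 1), bottleneck_dim >= 1)
  list(input_dim = input_dim, hidden_widths = as.integer(hidden_widths),
       bottleneck_dim = as.integer(bottleneck_dim),
       goi_head_hidden = as.integer(goi_head_hidden),
       activation = activation, lambda1 = lambda1, lambda2 = lambda2,
       lambda6_cosine = lambda6_cosine, n_targets = 0L)
}

#' Build an untrained model
#'
#' Initializes encoder, decoder and (when a [GOISpec-class] is given) the
#' genes-of-interest regression head with Kaiming-uniform weights and zero
#' biases, reproducibly from \code{seed}.
#'
#' @param input_dim number of input genes.
#' @param goi optional [GOISpec-class]; determines the head's output width.
#' @param config list from [sakuraConfig()].
#' @param seed integer seed for the initialization.
#' @return a [SakuraModel-class]
#' @export
sakuraModel <- function(input_dim, goi = NULL, config = sakuraConfig(),
                        seed = 1L) {
  config$input_dim <- as.integer(input_dim)
  if (config$bottleneck_dim > config$input_dim)
    stopf("bottleneck_dim must not exceed input_dim")
  n_t <- if (is.null(goi)) 0L else nTargets(goi)
  config$n_targets <- n_t
  enc_dims <- c(config$input_dim, config$hidden_widths, config$bottleneck_dim)
  dec_dims <- rev(enc_dims)
  params <- list(
    enc = with_seed(derive_seed(seed, "init", "enc"), init_stack(enc_dims)),
    dec = with_seed(derive_seed(seed, "init", "dec"), init_stack(dec_dims)),
    goi = if (n_t > 0L)
      with_seed(derive_seed(seed, "init", "goi"),
                init_stack(c(config$bottleneck_dim, config$goi_head_hidden, n_t)))
  )
  methods::new("SakuraModel", config = config, params = params,
               goi = if (is.null(goi)) list() else goi,
               history = data.frame())
}

#' Forward pass
#'
#' Deterministic given the parameters. The reconstruction is computed from
#' the embedding through the decoder, and the genes-of-interest prediction
#' from the embedding only (the head is attached to the bottleneck), so
#' decoder perturbations never change the embedding or the GOI prediction.
#'
#' @param model a [SakuraModel-class].
#' @param batch cells x input_dim matrix.
#' @return list with \code{embedding} (cells x bottleneck),
#'   \code{reconstruction} (cells x input_dim) and \code{goi_pred} (cells x
#'   n_targets, or NULL when the model has no head)
#' @export
sakuraForward <- function(model, batch) {
  batch <- as.matrix(batch)
  if (ncol(batch) != model@config$input_dim)
    stopf("batch has %d columns; model expects %d", ncol(batch),
          model@config$input_dim)
  act <- act_fun(model@config$activation)
  enc <- stack_forward(model@params$enc, batch, act)
  dec <- stack_forward(model@params$dec, enc$out, act)
  goi <- if (!is.null(model@params$goi))
    stack_forward(model@params$goi, enc$out, act)$out
  list(embedding = enc$out, reconstruction = dec$out, goi_pred = goi)
}

#' Reconstruction loss
#'
#' Sum over cells of \code{lambda1 * ||x - x'||_1 + lambda2 *
#' ||x - x'||_2^2} (the square applies to the Euclidean norm).
#'
#' @param x,x_hat cells x genes matrices of equal shape.
#' @param lambda1,lambda2 non-negative term weights.
#' @return non-negative scalar
#' @export
reconstructionLoss <- function(x, x_hat, lambda1 = 1, lambda2 = 1) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  if (!all(dim(x) == dim(x_hat))) stopf("shape mismatch")
  d <- x - x_hat
  lambda1 * sum(abs(d)) + lambda2 * sum(d^2)
}

#' Genes-of-interest regression loss
#'
#' Sum over cells of \code{lambda4 * L1 + lambda5 * squared L2 + lambda6 *
#' (1 - cosine similarity)} between the observed and predicted target
#' vectors. The cosine term is computed once per cell over its
#' target-vector (for a single target this reduces to a sign-agreement
#' term); vector norms carry an epsilon guard, and a cell whose observed
#' and predicted vectors are both all-zero contributes cosine term 0.
#'
#' @param y,y_hat cells x targets matrices.
#' @param lambda4,lambda5,lambda6 non-negative term weights.
#' @param eps norm guard (default 1e-8).
#' @return non-negative scalar
#' @export
goiLoss <- function(y, y_hat, lambda4 = 1, lambda5 = 1, lambda6 = 1,
                    eps = 1e-8) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!all(dim(y) == dim(y_hat))) stopf("shape mismatch")
  d <- y - y_hat
  out <- lambda4 * sum(abs(d)) + lambda5 * sum(d^2)
  if (lambda6 > 0) {
    ny <- sqrt(rowSums(y^2)); nyh <- sqrt(rowSums(y_hat^2))
    cosim <- rowSums(y * y_hat) / ((ny + eps) * (nyh + eps))
    cos_term <- 1 - cosim
    cos_term[ny == 0 & nyh == 0] <- 0
    out <- out + lambda6 * sum(cos_term)
  }
  out
}

# gradient of goiLoss w.r.t. y_hat (same conventions as goiLoss)
goi_loss_grad <- function(y, y_hat, lambda4, lambda5, lambda6, eps = 1e-8) {
  d <- y - y_hat
  g <- -lambda4 * sign(d) - 2 * lambda5 * d
  if (lambda6 > 0) {
    ny <- sqrt(rowSums(y^2)); nyh <- sqrt(rowSums(y_hat^2))
    denom <- (ny + eps) * (nyh + eps)
    cosim <- rowSums(y * y_hat) / denom
    # d(1 - cos)/d y_hat = -( y/denom - cos * y_hat/((nyh+eps)*nyh) )
    scale2 <- ifelse(nyh > 0, cosim / ((nyh + eps) * nyh), 0)
    gc <- -(y / denom - y_hat * scale2)
    gc[ny == 0 & nyh == 0, ] <- 0
    g <- g + lambda6 * gc
  }
  g
}

#' Total loss
#'
#' Plain sum of the reconstruction, regularization and genes-of-interest
#' components (each already carrying its own weights). Dropping the
#' regularization component is equivalent to \code{lambda3 = 0}.
#'
#' @param rec,reg,goi non-negative component values.
#' @return their sum
#' @export
totalLoss <- function(rec, reg = 0, goi = 0) rec + reg + goi

#' Save / load a model checkpoint
#'
#' A single-file checkpoint holding the architecture configuration, the
#' genes-of-interest specification, all parameter tensors and the training
#' history, under a versioned schema id.
#'
#' @param model a [SakuraModel-class].
#' @param path checkpoint file path (RDS).
#' @return `saveSakuraModel` returns the path invisibly;
#'   `readSakuraModel` the restored [SakuraModel-class].
#' @export
saveSakuraModel <- function(model, path) {
  stopifnot(methods::is(model, "SakuraModel"))
  saveRDS(list(schema = "sakura-model-v1", config = model@config,
               goi = model@goi, params = model@params,
               history = model@history), path)
  invisible(path)
}

#' @rdname saveSakuraModel
#' @export
readSakuraModel <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, "sakura-model-v1"))
    stopf("unrecognized checkpoint schema '%s'", ck$schema %||% "<none>")
  methods::new("SakuraModel", config = ck$config, params = ck$params,
               goi = ck$goi, history = ck$history)
}
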