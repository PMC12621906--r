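#' Sliced 2-Wasserstein distance between two point samples
#'
#' Draws \code{n_slices} unit directions uniformly on the unit sphere,
#' projects both samples onto each direction, and computes the exact 1-D
#' squared 2-Wasserstein distance between the projected samples by pairing
#' order statistics. Returns the square root of the mean per-slice squared
#' distance (the metric convention; use \code{squared = TRUE} for the
#' squared form).
#'
#' @param A,B n x d matrices with the same number of rows (equal sample
#'   sizes; resample beforehand if needed).
#' @param n_slices number of random projections (default 50).
#' @param seed integer seed for the slice directions.
#' @param squared return the squared distance instead of the metric.
#' @return non-negative scalar
#' @export
slicedW2 <- function(A, B, n_slices = 50, seed = 1L, squared = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stopf("empty sample")
  if (nrow(A) != nrow(B)) stopf("samples must have equal sizes")
  if (ncol(A) != ncol(B)) stopf("dimension mismatch")
  theta <- slice_directions(ncol(A), n_slices, seed)
  PA <- A %*% theta                      # n x n_slices projections
  PB <- B %*% theta
  msq <- mean(vapply(seq_len(n_slices), function(l)
    mean((sort(PA[, l]) - sort(PB[, l]))^2), 0))
  if (squared) msq else sqrt(msq)
}

slice_directions <- function(d, n_slices, seed) {
  with_seed(seed, {
    th <- matrix(rnorm(d * n_slices), d, n_slices)
    th / rep(sqrt(colSums(th^2)), each = d)
  })
}

# slicedW2 plus its gradient with respect to A (metric convention);
# used inside the training loop.
sliced_w2_with_grad <- function(A, B, n_slices, seed) {
  theta <- slice_directions(ncol(A), n_slices, seed)
  n <- nrow(A)
  PA <- A %*% theta
  PB <- B %*% theta
  coef <- matrix(0, n, n_slices)       # d(msq)/d(PA)
  msq <- 0
  for (l in seq_len(n_slices)) {
    oa <- order(PA[, l]); ob <- order(PB[, l])
    diff <- PA[oa, l] - PB[ob, l]
    msq <- msq + mean(diff^2)
    coef[oa, l] <- 2 * diff / (n * n_slices)
  }
  msq <- msq / n_slices
  value <- sqrt(msq)
  grad <- if (msq > 0) (coef %*% t(theta)) / (2 * value) else A * 0
  list(value = value, grad = grad)
}

#' Uniform latent prior
#'
#' The prior the embedding distribution is matched to:
#' \code{Uniform(-k, k)} independently in every embedding dimension. The
#' uniform box prevents representation collapse and encourages use of the
#' whole latent volume.
#'
#' @param k half-width of the box per dimension (default 5).
#' @param dims embedding dimensionality.
#' @return a list describing the prior
#' @export
priorSpec <- function(k = 5, dims = 50) {
  stopifnot(k > 0, dims >= 1)
  list(kind = "uniform", k = k, dims = as.integer(dims))
}

sample_prior <- function(prior, n, seed) {
  with_seed(seed,
    matrix(runif(n * prior$dims, -prior$k, prior$k), n, prior$dims))
}

#' Regularization loss
#'
#' \code{lambda3} times the sliced 2-Wasserstein distance between the
#' batch embedding and a fresh seeded sample of the same size from the
#' uniform prior.
#'
#' @param embedding batch x dims matrix.
#' @param prior from [priorSpec()]; \code{prior$dims} must equal
#'   \code{ncol(embedding)}.
#' @param lambda3 non-negative weight.
#' @param n_slices,seed passed to [slicedW2()]; the prior sample uses a
#'   seed derived from \code{seed}.
#' @param squared use the squared distance.
#' @return non-negative scalar
#' @export
regLoss <- function(embedding, prior = priorSpec(dims = ncol(embedding)),
                    lambda3 = 1, n_slices = 50, seed = 1L, squared = FALSE) {
  embedding <- as.matrix(embedding)
  if (prior$dims != ncol(embedding))
    stopf("prior dims (%d) != embedding dims (%d)", prior$dims,
          ncol(embedding))
  if (lambda3 == 0) return(0)
  P <- sample_prior(prior, nrow(embedding), derive_seed(seed, "prior"))
  lambda3 * slicedW2(embedding, P, n_slices, derive_seed(seed, "slices"),
                     squared = squared)
}
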