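# Minimal dense-network machinery on BLAS matrix ops. Layers are
# list(W, b) with W (in x out); batches are cells x features. Written here
# rather than delegated because the trained objective (joint reconstruction
# + sliced-Wasserstein prior + knowledge-head regression) needs custom
# gradients end to end; correctness is pinned by finite-difference tests.

celu <- function(v) pmax(v, 0) + pmin(0, exp(pmin(v, 0)) - 1)
celu_grad <- function(v) ifelse(v > 0, 1, exp(pmin(v, 0)))

act_fun <- function(name) {
  switch(name,
    celu = list(f = celu, g = celu_grad),
    identity = list(f = identity, g = function(v) 1),
    stopf("unknown activation '%s'", name))
}

# Kaiming-uniform fan-in init, zero bias
init_layer <- function(n_in, n_out) {
  bound <- sqrt(6 / n_in)
  list(W = matrix(runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = rep(0, n_out))
}

init_stack <- function(dims) {
  lapply(seq_len(length(dims) - 1L),
         function(i) init_layer(dims[i], dims[i + 1L]))
}

# Forward through a layer stack; activation applied after every layer
# except the last (bottleneck and output layers stay linear).
# Returns list(out, cache) where cache holds pre-activations and inputs.
stack_forward <- function(layers, x, act) {
  L <- length(layers)
  zs <- vector("list", L)
  as <- vector("list", L + 1L)
  as[[1L]] <- x
  for (i in seq_len(L)) {
    z <- as[[i]] %*% layers[[i]]$W
    z <- sweep_add_rowvec(z, layers[[i]]$b)
    zs[[i]] <- z
    as[[i + 1L]] <- if (i < L) act$f(z) else z
  }
  list(out = as[[L + 1L]], zs = zs, as = as)
}

sweep_add_rowvec <- function(m, v) m + rep(v, each = nrow(m))

# Backward through a stack given dL/d(out). Returns list(grads, dx).
# grads[[i]] = list(W, b) matching layers.
stack_backward <- function(layers, cache, dout, act, need_dx = TRUE) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dout                       # dL/dz_L (last layer linear)
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = crossprod(cache$as[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) * act$g(cache$zs[[i - 1L]])
    } else if (need_dx) {
      delta <- delta %*% t(layers[[i]]$W)
    }
  }
  list(grads = grads, dx = if (need_dx) delta else NULL)
}

# ---- RMSProp ---------------------------------------------------------------

rmsprop_state <- function(layers) {
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

rmsprop_update <- function(layers, grads, state, lr, alpha, eps = 1e-8) {
  for (i in seq_along(layers)) {
    state[[i]]$W <- alpha * state[[i]]$W + (1 - alpha) * grads[[i]]$W^2
    state[[i]]$b <- alpha * state[[i]]$b + (1 - alpha) * grads[[i]]$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * grads[[i]]$W / (sqrt(state[[i]]$W) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * grads[[i]]$b / (sqrt(state[[i]]$b) + eps)
  }
  list(layers = layers, state = state)
}
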