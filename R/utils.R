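#' @import methods
#' @importFrom stats var sd rnorm runif rnbinom rpois rlnorm quantile
#'   hclust as.dist cutree ecdf wilcox.test setNames dist
#' @importFrom utils read.table write.table
NULL

# Derive a reproducible child seed from a base seed and a stream label.
# Keeps results independent across components (e.g. skipping the GOI pass
# does not shift the reconstruction batch order) and below 2^31.
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  # FNV-1a style 32-bit hash, folded into [0, 2^31 - 2]
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(labels)) {
    h <- bitwXor(as.integer(h), ch)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646L) + 1L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_matrix_like <- function(x, what = "x") {
  if (!(is.matrix(x) || methods::is(x, "Matrix")))
    stopf("'%s' must be a matrix", what)
  invisible(x)
}
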