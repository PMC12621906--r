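#' Genes-of-interest specification
#'
#' An ordered list of regression targets for the knowledge head. Each target
#' is a named function of gene expression columns: a single gene
#' (\code{kind = "gene"}), a sum of genes (\code{kind = "sum"}, e.g. the sum
#' of \emph{CD8A} and \emph{CD8B} as a proxy for the CD8 receptor), or the
#' per-cell minimum over a set of z-scored signature averages
#' (\code{kind = "min_signature_z"}, used e.g. to target cells that are high
#' in both a CDK-inhibitor score and an aging score).
#'
#' @slot targets a list; each element is a list with entries \code{name},
#'   \code{kind} (one of \code{"gene"}, \code{"sum"},
#'   \code{"min_signature_z"}), \code{genes} (character vector, used by
#'   \code{gene}/\code{sum}) and \code{signatures} (named list of character
#'   vectors, used by \code{min_signature_z}).
#'
#' @seealso [goiSpec()], [readGOISpec()], [buildGoiTargets()]
#' @export
setClass("GOISpec", representation(targets = "list"))

setValidity("GOISpec", function(object) {
  ts <- object@targets
  if (length(ts) == 0L) return("GOISpec must contain at least one target")
  kinds <- vapply(ts, function(t) t$kind %||% "", "")
  bad <- !kinds %in% c("gene", "sum", "min_signature_z")
  if (any(bad)) return(sprintf("unknown target kind '%s'", kinds[bad][1]))
  nms <- vapply(ts, function(t) t$name %||% "", "")
  if (anyDuplicated(nms)) return("target names must be unique")
  for (t in ts) {
    if (t$kind %in% c("gene", "sum") && length(t$genes) < 1L)
      return(sprintf("target '%s' has no member genes", t$name))
    if (t$kind == "gene" && length(t$genes) != 1L)
      return(sprintf("target '%s' of kind 'gene' must name exactly one gene", t$name))
    if (t$kind == "min_signature_z" && length(t$signatures) < 1L)
      return(sprintf("target '%s' has no signatures", t$name))
  }
  TRUE
})

#' Trained SAKURA model
#'
#' Parameter container for the knowledge-guided autoencoder: encoder,
#' decoder and genes-of-interest regression head, together with the
#' architecture hyperparameters, the loss weights and the training history.
#'
#' @slot config list of architecture and loss settings (see
#'   [sakuraConfig()]).
#' @slot params list with elements \code{enc}, \code{dec}, \code{goi}; each
#'   a list of linear layers \code{list(W, b)}.
#' @slot goi the [GOISpec-class] the head was trained against (may be an
#'   empty list-backed spec when the model is purely unsupervised).
#' @slot history data.frame of per-epoch loss components and lambda values.
#'
#' @export
setClass("SakuraModel",
  representation(config = "list", params = "list", goi = "ANY",
                 history = "data.frame"))

setValidity("SakuraModel", function(object) {
  p <- object@params
  if (!all(c("enc", "dec") %in% names(p)))
    return("params must contain encoder and decoder layer lists")
  n_t <- object@config$n_targets %||% 0L
  if (n_t > 0L) {
    if (is.null(p$goi)) return("model with GOI targets lacks a GOI head")
    out <- p$goi[[length(p$goi)]]
    if (ncol(out$W) != n_t)
      return("GOI head output width must equal the number of GOI targets")
  }
  TRUE
})

#' Per-cell cluster assignment
#'
#' Integer cluster ids (0-based, contiguous) for a set of cells, plus the
#' clustering parameters used.
#'
#' @slot cell_ids character vector of cell identifiers.
#' @slot cluster_of integer vector, same length, values in \code{[0, k)}.
#' @slot k number of clusters.
#' @slot params list of clustering parameters (n_neighbors, resolution,
#'   metric, seed) for provenance.
#'
#' @seealso [snnCluster()]
#' @export
setClass("ClusterAssignment",
  representation(cell_ids = "character", cluster_of = "integer",
                 k = "integer", params = "list"))

setValidity("ClusterAssignment", function(object) {
  if (length(object@cell_ids) != length(object@cluster_of))
    return("cell_ids and cluster_of lengths differ")
  if (anyDuplicated(object@cell_ids)) return("duplicate cell ids")
  k <- object@k
  cl <- object@cluster_of
  if (length(cl) == 0L) return("empty assignment")
  if (min(cl) < 0L || max(cl) >= k) return("cluster ids must lie in [0, k)")
  if (!all((seq_len(k) - 1L) %in% cl))
    return("every cluster id in [0, k) must appear at least once")
  TRUE
})

#' Evaluation report
#'
#' Keyed collection of named scalar evaluation measures (distinctiveness,
#' DBI, ASW, CHI, per-type precision/recall/F1, ARI, NMI) plus the metric
#' and labeling conventions that produced them.
#'
#' @slot scores named list of numeric scalars or named numeric vectors
#'   (per-gene / per-type breakdowns).
#' @slot meta list of conventions (distance metric, labeling rule, ...).
#'
#' @export
setClass("EvaluationReport",
  representation(scores = "list", meta = "list"))

# ---- constructors ----------------------------------------------------------

#' Construct a genes-of-interest specification
#'
#' @param ... targets; each argument is either a bare gene name (shorthand
#'   for an identity target) or a list with entries \code{name},
#'   \code{kind}, \code{genes}, \code{signatures}.
#' @param genes convenience: character vector of gene names, each becoming
#'   an identity target.
#' @return a [GOISpec-class]
#' @examples
#' goiSpec(genes = c("INS", "GCG"))
#' goiSpec(list(name = "CD8", kind = "sum", genes = c("CD8A", "CD8B")))
#' @export
goiSpec <- function(..., genes = NULL) {
  raw <- list(...)
  targets <- list()
  for (g in genes)
    targets[[length(targets) + 1L]] <-
      list(name = g, kind = "gene", genes = g, signatures = NULL)
  for (t in raw) {
    if (is.character(t) && length(t) == 1L)
      t <- list(name = t, kind = "gene", genes = t, signatures = NULL)
    t$signatures <- t$signatures %||% NULL
    t$genes <- t$genes %||% character()
    targets[[length(targets) + 1L]] <- t
  }
  methods::new("GOISpec", targets = targets)
}

#' @describeIn goiSpec number of regression targets
#' @param spec a [GOISpec-class]
#' @export
nTargets <- function(spec) length(spec@targets)

#' @describeIn goiSpec target names, in order
#' @export
goiNames <- function(spec) vapply(spec@targets, function(t) t$name, "")

#' All gene ids referenced anywhere in a specification
#' @param spec a [GOISpec-class]
#' @return character vector of unique gene identifiers
#' @export
goiGenes <- function(spec) {
  unique(unlist(lapply(spec@targets, function(t)
    c(t$genes, unlist(t$signatures, use.names = FALSE)))))
}

clusterAssignment <- function(cell_ids, cluster_of, params = list()) {
  cluster_of <- as.integer(cluster_of)
  methods::new("ClusterAssignment", cell_ids = as.character(cell_ids),
               cluster_of = cluster_of, k = max(cluster_of) + 1L,
               params = params)
}

#' Accessors for cluster assignments
#'
#' @param x a [ClusterAssignment-class]
#' @return \code{clusterIds} returns the 0-based integer cluster id per
#'   cell, named by cell id; \code{nClusters} the number of clusters.
#' @export
clusterIds <- function(x) setNames(x@cluster_of, x@cell_ids)

#' @rdname clusterIds
#' @export
nClusters <- function(x) x@k

#' @rdname clusterIds
#' @export
cellIds <- function(x) x@cell_ids

#' Scores stored in an evaluation report
#' @param x an [EvaluationReport-class]
#' @param name optional score name; when missing, the full named list.
#' @export
reportScores <- function(x, name = NULL) {
  if (is.null(name)) x@scores else x@scores[[name]]
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "GOISpec", function(object) {
  cat(sprintf("GOISpec with %d target(s):\n", nTargets(object)))
  for (t in object@targets) {
    desc <- switch(t$kind,
      gene = t$genes,
      sum  = paste(t$genes, collapse = " + "),
      min_signature_z = sprintf("min-z over %d signature(s)",
                                length(t$signatures)))
    cat(sprintf("  %s [%s]: %s\n", t$name, t$kind, desc))
  }
})

setMethod("show", "SakuraModel", function(object) {
  cfg <- object@config
  cat("SakuraModel\n")
  cat(sprintf("  input: %d genes -> bottleneck: %d\n",
              cfg$input_dim, cfg$bottleneck_dim))
  cat(sprintf("  hidden widths: %s | activation: %s\n",
              paste(cfg$hidden_widths, collapse = "/"), cfg$activation))
  cat(sprintf("  GOI targets: %d | trained epochs: %d\n",
              cfg$n_targets %||% 0L, nrow(object@history)))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters\n",
              length(object@cell_ids), object@k))
  tab <- table(object@cluster_of)
  cat("  sizes:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
      "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  for (nm in names(object@scores)) {
    v <- object@scores[[nm]]
    if (length(v) == 1L && is.numeric(v))
      cat(sprintf("  %s: %.4f\n", nm, v))
    else
      cat(sprintf("  %s: <%d values>\n", nm, length(v)))
  }
  if (length(object@meta))
    cat("  conventions:", paste(names(object@meta),
        vapply(object@meta, function(z) paste(format(z), collapse = ","), ""),
        sep = "=", collapse = " "), "\n")
})
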