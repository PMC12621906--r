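#' Clusters expressing a single gene of interest
#'
#' A gene of interest counts as expressed in a cluster when its detection
#' rate is at least \code{hi_thresh}; a cluster is single-GOI when exactly
#' one gene is expressed and every other gene's detection rate is at most
#' \code{lo_thresh}. Used to call e.g. hormone-specific islet endocrine
#' clusters.
#'
#' @inheritParams detectionRates
#' @param hi_thresh detection rate at or above which a gene counts as
#'   expressed (default 0.5).
#' @param lo_thresh detection rate at or below which a gene counts as
#'   absent (default 0.1).
#' @return list per cluster (named by cluster id) with \code{expressed}
#'   (character vector of expressed genes) and \code{single} (logical)
#' @export
singleGoiClusters <- function(sce, assignment, genes, hi_thresh = 0.5,
                              lo_thresh = 0.1) {
  rates <- detectionRates(sce, assignment, genes)
  out <- lapply(seq_len(ncol(rates)), function(j) {
    r <- rates[, j]
    expressed <- names(r)[r >= hi_thresh]
    single <- length(expressed) == 1L &&
      all(r[setdiff(names(r), expressed)] <= lo_thresh)
    list(expressed = expressed, single = single)
  })
  setNames(out, colnames(rates))
}

#' Per-cell quality-control pass
#'
#' Thresholds for the three QC metrics (total reads, total UMIs, detected
#' genes) are the given percentile (nearest-rank) over non-doublet cells
#' only; a cell passes when all three metrics are strictly above their
#' thresholds. A cell in the lowest 30 percentile on any metric is
#' considered potentially problematic.
#'
#' @param qc data.frame with columns \code{total_reads}, \code{total_umi},
#'   \code{n_genes} and \code{doublet_votes} (0-3).
#' @param percentile percentage in \code{[0, 100]} (default 30).
#' @return logical vector, one per row of \code{qc}
#' @export
qcPass <- function(qc, percentile = 30) {
  need <- c("total_reads", "total_umi", "n_genes", "doublet_votes")
  miss <- setdiff(need, names(qc))
  if (length(miss)) stopf("qc table lacks columns: %s",
                          paste(miss, collapse = ", "))
  nd <- qc$doublet_votes == 0
  if (!any(nd)) stopf("no non-doublet cells")
  pass <- rep(TRUE, nrow(qc))
  for (col in c("total_reads", "total_umi", "n_genes")) {
    thr <- nearest_rank_percentile(qc[[col]][nd], percentile)
    pass <- pass & qc[[col]] > thr
  }
  pass
}

# nearest-rank percentile; p = 0 gives -Inf so that every cell passes
nearest_rank_percentile <- function(x, p) {
  if (p <= 0) return(-Inf)
  sort(x)[ceiling(p / 100 * length(x))]
}

#' Combine external doublet calls
#' @param ... logical vectors, one per doublet-detection method.
#' @return integer vector of votes (how many methods called doublet)
#' @export
combineDoubletVotes <- function(...) {
  votes <- Reduce(`+`, lapply(list(...), as.integer))
  as.integer(votes)
}

#' Knowledge-guided annotation refinement
#'
#' Refines cell annotations inside clusters dominated by a broad label
#' (e.g. "islet endocrine cells"):
#' \enumerate{
#'   \item restrict to clusters with more than 50 percent of cells
#'     carrying \code{broad_label};
#'   \item unlabeled cells there that no doublet method flagged and that
#'     pass the QC percentile filter are provisionally given
#'     \code{broad_label};
#'   \item any broad-labeled cell (original or provisional) in a cluster
#'     expressing exactly one gene of interest receives that gene's
#'     subtype label;
#'   \item cells in any GOI-expressing cluster that carry a different
#'     prior label are flagged suspicious (the original annotation is
#'     questioned, not asserted wrong).
#' }
#'
#' @inheritParams singleGoiClusters
#' @param qc data.frame as in [qcPass()], rows aligned with the
#'   assignment's cells.
#' @param prior_labels character vector of prior annotations (NA for
#'   unlabeled), aligned with the assignment's cells.
#' @param broad_label the broad annotation being refined.
#' @param subtype_map named character vector gene -> subtype label;
#'   defaults to \code{paste(gene, "cell")}.
#' @param percentile QC percentile (default 30).
#' @return data.frame with columns \code{cell_id}, \code{action}
#'   (\code{new_subtype}, \code{broad_to_subtype}, \code{suspicious},
#'   \code{unchanged}), \code{assigned_label}, \code{reasons}
#' @export
refineAnnotations <- function(sce, assignment, genes, qc, prior_labels,
                              broad_label, subtype_map = NULL,
                              hi_thresh = 0.5, lo_thresh = 0.1,
                              percentile = 30) {
  M <- length(assignment@cell_ids)
  stopifnot(nrow(qc) == M, length(prior_labels) == M)
  if (!broad_label %in% prior_labels)
    stopf("broad label '%s' absent from prior annotations", broad_label)
  if (is.null(subtype_map))
    subtype_map <- setNames(paste(genes, "cell"), genes)
  goi_info <- singleGoiClusters(sce, assignment, genes, hi_thresh, lo_thresh)
  cl <- assignment@cluster_of
  cl_chr <- as.character(cl)

  # rule 1: clusters dominated by the broad label
  frac_broad <- vapply(.cluster_members(assignment), function(ix)
    mean(prior_labels[ix] %in% broad_label), 0)   # NA priors count against
  dominated <- names(frac_broad)[frac_broad > 0.5]

  # GOI-expressing clusters (one or more expressed genes)
  expressing <- names(goi_info)[vapply(goi_info, function(g)
    length(g$expressed) >= 1L, TRUE)]
  single_goi <- names(goi_info)[vapply(goi_info, function(g) g$single, TRUE)]

  qc_ok <- qcPass(qc, percentile)
  clean <- qc$doublet_votes == 0 & qc_ok

  action <- rep("unchanged", M)
  assigned <- prior_labels
  reasons <- character(M)

  # rule 2: promote unlabeled clean cells in dominated clusters
  provisional_broad <- is.na(prior_labels) & cl_chr %in% dominated & clean
  has_broad <- provisional_broad |
    (!is.na(prior_labels) & prior_labels == broad_label)

  for (i in seq_len(M)) {
    in_single <- cl_chr[i] %in% single_goi
    in_expr <- cl_chr[i] %in% expressing
    if (has_broad[i] && in_single) {
      gene <- goi_info[[cl_chr[i]]]$expressed
      assigned[i] <- subtype_map[[gene]]
      if (provisional_broad[i]) {
        action[i] <- "new_subtype"
        reasons[i] <- "unlabeled;clean;single_goi_cluster"
      } else {
        action[i] <- "broad_to_subtype"
        reasons[i] <- "broad_prior;single_goi_cluster"
      }
    } else if (in_expr && !is.na(prior_labels[i]) &&
               prior_labels[i] != broad_label &&
               !prior_labels[i] %in% subtype_map) {
      action[i] <- "suspicious"
      reasons[i] <- "non_matching_prior;goi_expressing_cluster"
    } else if (provisional_broad[i]) {
      # promoted to broad only (cluster dominated but not single-GOI)
      action[i] <- "new_subtype"
      assigned[i] <- broad_label
      reasons[i] <- "unlabeled;clean;broad_cluster"
    }
  }
  data.frame(cell_id = assignment@cell_ids, action = action,
             assigned_label = assigned, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Gene-signature scores with top-decile flags
#'
#' Per signature: per-cell mean of per-gene z-scores of log-normalized
#' expression, re-z-scored across cells (population standard deviation
#' throughout). Cells in the top 10 percent per signature are flagged, and
#' pairwise co-occurrence counts of the flags are reported for Venn-style
#' summaries.
#'
#' @param sce container with assay \code{"lognorm"} (or a genes x cells
#'   matrix).
#' @param signatures named list of gene-id vectors; each needs at least
#'   one gene with nonzero variance.
#' @param top_fraction flag fraction (default 0.1).
#' @return list with \code{scores} (cells x signatures), \code{top}
#'   (logical cells x signatures), \code{co_occurrence} (signatures x
#'   signatures counts)
#' @export
signatureScores <- function(sce, signatures, top_fraction = 0.1) {
  ln <- .lognorm_matrix(sce, "signatureScores")
  stopifnot(is.list(signatures), length(signatures) >= 1)
  if (is.null(names(signatures)))
    names(signatures) <- paste0("sig", seq_along(signatures))
  M <- ncol(ln)
  scores <- vapply(names(signatures), function(nm)
    sig_score(ln, signatures[[nm]], label = nm), numeric(M))
  rownames(scores) <- colnames(ln)
  top <- apply(scores, 2, function(s)
    s > quantile(s, 1 - top_fraction, type = 1))
  co <- crossprod(top * 1L)
  list(scores = scores, top = top, co_occurrence = co)
}
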