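#' Simulation parameters
#'
#' Describes a synthetic scRNA-seq scenario: a few major populations, and
#' optionally rare subpopulations that share their parent's expression
#' program except for a handful of marker genes; sparse non-negative
#' counts from a negative binomial with lognormal library sizes; optional
#' doublet-like cells and hidden labels.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param populations data.frame with columns \code{name},
#'   \code{fraction} (summing to 1), \code{parent} (NA for top-level
#'   populations).
#' @param log_fold_changes named list: population -> named numeric vector
#'   of log-fold changes on specific genes, relative to the baseline
#'   program. Subpopulations inherit their parent's vector before their
#'   own is applied.
#' @param base_log_mean,gene_log_sd per-gene baseline log-rates are drawn
#'   from Normal(base_log_mean, gene_log_sd); rates are normalized within
#'   each population, so only relative values matter.
#' @param dispersion negative-binomial size parameter r (variance
#'   mu + mu^2/r); \code{Inf} gives the Poisson limit.
#' @param library_size_log_mean,library_size_log_sd lognormal library
#'   sizes.
#' @param dropout_midpoint,dropout_slope optional logistic dropout on the
#'   per-entry mean (both NULL disables it; off by default since
#'   negative-binomial sparsity suffices at these depths).
#' @param doublet_rate fraction of cells replaced by doublets (average of
#'   two random cells' rate vectors, counts resampled).
#' @param unlabeled_rate fraction of cells whose labels are hidden in the
#'   truth table.
#' @param seed integer seed; all randomness derives from it.
#' @return a named list of parameters
#' @export
simulationParams <- function(n_cells = 2000L, n_genes = 1000L,
                             populations = data.frame(
                               name = c("typeA", "typeB"),
                               fraction = c(0.5, 0.5),
                               parent = NA_character_),
                             log_fold_changes = list(),
                             base_log_mean = 0, gene_log_sd = 1,
                             dispersion = 2,
                             library_size_log_mean = log(5000),
                             library_size_log_sd = 0.3,
                             dropout_midpoint = NULL, dropout_slope = NULL,
                             doublet_rate = 0, unlabeled_rate = 0,
                             seed = 1L) {
  if (abs(sum(populations$fraction) - 1) > 1e-9)
    stopf("population fractions must sum to 1")
  # fraction 0 marks a template population (e.g. a shared parent program)
  if (any(populations$fraction < 0)) stopf("fractions must be non-negative")
  if (doublet_rate < 0 || doublet_rate >= 1 ||
      unlabeled_rate < 0 || unlabeled_rate >= 1)
    stopf("rates must lie in [0, 1)")
  as.list(environment())
}

#' Simulate a count matrix with known structure
#'
#' @param params list from [simulationParams()].
#' @return list with \code{sce} (a \linkS4class{SingleCellExperiment}
#'   with assay \code{"counts"}) and \code{truth} (data.frame: cell_id,
#'   population, parent, is_doublet, observed_label with NA where hidden)
#' @export
simulateCounts <- function(params) {
  seed <- params$seed
  M <- params$n_cells; N <- params$n_genes
  gene_ids <- sprintf("g%04d", seq_len(N))
  cell_ids <- sprintf("cell%05d", seq_len(M))
  pops <- params$populations

  base <- with_seed(derive_seed(seed, "genes"),
                    rnorm(N, params$base_log_mean, params$gene_log_sd))
  names(base) <- gene_ids

  # per-population normalized gene programs (subpopulations inherit parent)
  lfc_of <- function(pop) {
    v <- numeric(N); names(v) <- gene_ids
    parent <- pops$parent[pops$name == pop]
    if (!is.na(parent)) v <- lfc_of(parent)
    own <- params$log_fold_changes[[pop]]
    if (!is.null(own)) {
      miss <- setdiff(names(own), gene_ids)
      if (length(miss)) stopf("log-fold-change genes outside universe: %s",
                              paste(miss, collapse = ", "))
      v[names(own)] <- v[names(own)] + own
    }
    v
  }
  progs <- vapply(pops$name, function(p) {
    r <- exp(base + lfc_of(p))
    r / sum(r)
  }, numeric(N))                                   # genes x populations

  live <- pops$fraction > 0
  pop_of <- with_seed(derive_seed(seed, "pops"),
                      sample(pops$name[live], M, replace = TRUE,
                             prob = pops$fraction[live]))
  libs <- with_seed(derive_seed(seed, "libs"),
                    rlnorm(M, params$library_size_log_mean,
                           params$library_size_log_sd))
  mu <- progs[, pop_of, drop = FALSE] *
    rep(libs, each = N)                            # genes x cells means

  is_doublet <- rep(FALSE, M)
  if (params$doublet_rate > 0) {
    n_db <- round(params$doublet_rate * M)
    slots <- with_seed(derive_seed(seed, "dbl-slots"), sample.int(M, n_db))
    pair <- with_seed(derive_seed(seed, "dbl-pairs"),
                      matrix(sample.int(M, 2 * n_db, replace = TRUE), n_db))
    mu[, slots] <- (mu[, pair[, 1]] + mu[, pair[, 2]]) / 2
    is_doublet[slots] <- TRUE
  }

  counts <- with_seed(derive_seed(seed, "counts"), {
    if (is.infinite(params$dispersion))
      matrix(rpois(N * M, as.vector(mu)), N, M)
    else
      matrix(rnbinom(N * M, mu = as.vector(mu), size = params$dispersion),
             N, M)
  })
  if (!is.null(params$dropout_midpoint) && !is.null(params$dropout_slope)) {
    pdrop <- 1 / (1 + exp(params$dropout_slope *
                            (log(pmax(as.vector(mu), 1e-12)) -
                               params$dropout_midpoint)))
    keep <- with_seed(derive_seed(seed, "dropout"),
                      matrix(runif(N * M) >= pdrop, N, M))
    counts <- counts * keep
  }
  dimnames(counts) <- list(gene_ids, cell_ids)

  observed <- pop_of
  if (params$unlabeled_rate > 0) {
    hide <- with_seed(derive_seed(seed, "hide"),
                      sample.int(M, round(params$unlabeled_rate * M)))
    observed[hide] <- NA
  }
  truth <- data.frame(
    cell_id = cell_ids, population = pop_of,
    parent = pops$parent[match(pop_of, pops$name)],
    is_doublet = is_doublet, observed_label = observed,
    stringsAsFactors = FALSE)
  list(sce = newExpressionMatrix(Matrix::Matrix(counts, sparse = TRUE)),
       truth = truth)
}

#' Packaged desk-scale scenarios
#'
#' Deterministic seeded fixtures mirroring the regimes the method targets:
#' \describe{
#'   \item{rare_subtype}{2000 cells x 1000 genes; three major types (40,
#'     30, 25 percent) each with a 40-gene program, plus a 5 percent
#'     subtype of the largest type that differs from its parent only in 5
#'     marker genes (log-fold change 2). The markers are the genes of
#'     interest.}
#'   \item{two_similar_subtypes}{one major type and two 25 percent
#'     subtypes of a second type that share its program and differ only in
#'     their own 5-marker sets.}
#'   \item{senescence_scores}{1000 cells x 500 genes; a 5 percent
#'     subpopulation jointly elevates a 7-gene CDK-inhibitor-like
#'     signature and a 10-gene aging-like signature (log-fold change
#'     1.5).}
#'   \item{annotation_toy}{20 hand-written cells in 2 fixed clusters with
#'     prior labels, QC metrics and doublet votes, small enough to check
#'     the annotation-refinement rules by hand.}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed (default 7).
#' @return list with \code{sce}, \code{truth}, and scenario extras
#'   (\code{goi}, \code{markers}, \code{signatures}, \code{clusters},
#'   \code{qc}, \code{prior_labels}, \code{params} as applicable)
#' @export
makeFixture <- function(name = c("rare_subtype", "two_similar_subtypes",
                                 "senescence_scores", "annotation_toy"),
                        seed = 7L) {
  name <- match.arg(name)
  if (name == "rare_subtype") {
    # major types differ broadly (150 genes at log-fold change 1.5, as
    # distinct real cell types do); the rare subtype differs from its
    # parent only in 5 marker genes at log-fold change 2
    markers <- sprintf("g%04d", 901:905)
    progs <- list(
      typeA = setNames(rep(1.5, 150), sprintf("g%04d", 1:150)),
      typeB = setNames(rep(1.5, 150), sprintf("g%04d", 151:300)),
      typeC = setNames(rep(1.5, 150), sprintf("g%04d", 301:450)),
      typeA_rare = setNames(rep(2, 5), markers))
    params <- simulationParams(
      n_cells = 2000L, n_genes = 1000L,
      populations = data.frame(
        name = c("typeA", "typeB", "typeC", "typeA_rare"),
        fraction = c(0.40, 0.30, 0.25, 0.05),
        parent = c(NA, NA, NA, "typeA")),
      log_fold_changes = progs, seed = seed)
    sim <- simulateCounts(params)
    return(c(sim, list(goi = goiSpec(genes = markers), markers = markers,
                       params = params)))
  }
  if (name == "two_similar_subtypes") {
    mk1 <- sprintf("g%04d", 901:905); mk2 <- sprintf("g%04d", 906:910)
    params <- simulationParams(
      n_cells = 2000L, n_genes = 1000L,
      populations = data.frame(
        name = c("typeA", "typeB", "typeB1", "typeB2"),
        fraction = c(0.50, 0, 0.25, 0.25),
        parent = c(NA, NA, "typeB", "typeB")),
      log_fold_changes = list(
        typeA = setNames(rep(1.5, 150), sprintf("g%04d", 1:150)),
        typeB = setNames(rep(1.5, 150), sprintf("g%04d", 151:300)),
        typeB1 = setNames(rep(2, 5), mk1),
        typeB2 = setNames(rep(2, 5), mk2)),
      seed = seed)
    sim <- simulateCounts(params)
    return(c(sim, list(goi = goiSpec(genes = c(mk1, mk2)),
                       markers = list(typeB1 = mk1, typeB2 = mk2),
                       params = params)))
  }
  if (name == "senescence_scores") {
    # genes 1-7 act as the CDK-inhibitor signature, 8-17 as the aging one
    lfc <- setNames(rep(1.5, 17), sprintf("g%04d", 1:17))
    params <- simulationParams(
      n_cells = 1000L, n_genes = 500L,
      populations = data.frame(
        name = c("base", "senescent"), fraction = c(0.95, 0.05),
        parent = c(NA, "base")),
      log_fold_changes = list(senescent = lfc), seed = seed)
    sim <- simulateCounts(params)
    sig <- list(cdki = sprintf("g%04d", 1:7), aging = sprintf("g%04d", 8:17))
    return(c(sim, list(signatures = sig,
                       goi = goiSpec(list(name = "senescence",
                                          kind = "min_signature_z",
                                          genes = character(),
                                          signatures = sig)),
                       params = params)))
  }
  annotation_toy_fixture()
}

# 20 hand-written cells: cluster 0 is a single-GOI (INS) cluster dominated
# by the broad label; cluster 1 expresses two hormones. Values are chosen
# so the refinement rules can be walked through by hand.
annotation_toy_fixture <- function() {
  genes <- c("INS", "GCG", "SST", "PPY", "GHRL",
             sprintf("HK%d", 1:5))
  cells <- sprintf("c%02d", 1:20)
  counts <- matrix(0L, length(genes), length(cells),
                   dimnames = list(genes, cells))
  counts[sprintf("HK%d", 1:5), ] <- 3L              # housekeeping floor
  # cluster 0 = c01..c12: INS in 11/12 cells (c07 zero), no other hormone
  counts["INS", sprintf("c%02d", 1:12)] <- 5L
  counts["INS", "c07"] <- 0L
  # cluster 1 = c13..c20: GCG in 5/8, SST in 4/8
  counts["GCG", sprintf("c%02d", 13:17)] <- 4L
  counts["SST", sprintf("c%02d", 17:20)] <- 4L
  clusters <- clusterAssignment(cells, c(rep(0L, 12), rep(1L, 8)))
  broad <- "islet endocrine cells"
  prior <- c(rep(broad, 7),                     # c01..c07
             NA, NA, NA, NA,                    # c08 (QC-fail), c09, c10, c11 (doublet)
             "acinar cells",                    # c12
             rep(broad, 4),                     # c13..c16
             rep("acinar cells", 3),            # c17..c19
             NA)                                # c20
  # QC metrics: c08 lowest, then c01..c07, c11..c20, with c09/c10 highest
  rank_of <- c(2:8,            # c01..c07
               1,              # c08
               19, 20,         # c09, c10
               9:18)           # c11..c20
  qc <- data.frame(
    cell_id = cells,
    total_reads = 10000 + 500 * rank_of,
    total_umi = 1000 + 100 * rank_of,
    n_genes = 200 + 10 * rank_of,
    doublet_votes = ifelse(cells == "c11", 1L, 0L))
  list(sce = newExpressionMatrix(counts), truth = NULL,
       clusters = clusters, goi = goiSpec(genes = genes[1:5]),
       goi_genes = genes[1:5], qc = qc, prior_labels = prior,
       broad_label = broad)
}
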