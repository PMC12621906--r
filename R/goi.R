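#' Build the regression target matrix for the genes of interest
#'
#' Evaluates every target of a [GOISpec-class] on the log-normalized
#' expression values, producing the cells x targets matrix the knowledge
#' head regresses against.
#'
#' Target kinds:
#' \describe{
#'   \item{gene}{the gene's log-normalized column, unchanged.}
#'   \item{sum}{the per-cell sum of the member genes' columns (e.g.
#'     \emph{CD8A} + \emph{CD8B}).}
#'   \item{min_signature_z}{for each member signature, the per-cell mean of
#'     z-scored member gene columns is itself z-scored across cells; the
#'     target is the per-cell minimum over signatures (e.g. min of a
#'     CDK-inhibitor score and an aging score). Z-scores use the population
#'     standard deviation.}
#' }
#'
#' @param sce container with assay \code{"lognorm"}, or a genes x cells
#'   matrix of log-normalized values.
#' @param spec a [GOISpec-class]; all referenced genes must be present.
#' @return cells x targets numeric matrix, columns named by target
#' @export
buildGoiTargets <- function(sce, spec) {
  ln <- if (methods::is(sce, "SummarizedExperiment"))
    as.matrix(.get_assay(sce, "lognorm", "buildGoiTargets")) else as.matrix(sce)
  stopifnot(methods::is(spec, "GOISpec"))
  miss <- setdiff(goiGenes(spec), rownames(ln))
  if (length(miss))
    stopf("genes of interest absent from the matrix: %s",
          paste(miss, collapse = ", "))
  M <- ncol(ln)
  out <- matrix(0, M, nTargets(spec),
                dimnames = list(colnames(ln), goiNames(spec)))
  for (j in seq_along(spec@targets)) {
    t <- spec@targets[[j]]
    out[, j] <- switch(t$kind,
      gene = ln[t$genes, ],
      sum  = colSums(ln[t$genes, , drop = FALSE]),
      min_signature_z = {
        scores <- vapply(names(t$signatures) %||% seq_along(t$signatures),
          function(snm) {
            sig_score(ln, t$signatures[[snm]],
                      label = sprintf("%s/%s", t$name, snm))
          }, numeric(M))
        apply(scores, 1, min)
      })
  }
  out
}

# z-score of the per-cell mean of per-gene z-scores (population sd)
sig_score <- function(ln, genes, label = "signature") {
  miss <- setdiff(genes, rownames(ln))
  if (length(miss)) stopf("signature '%s': genes absent: %s", label,
                          paste(miss, collapse = ", "))
  sub <- ln[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  s <- sqrt(rowMeans((sub - mu)^2))
  ok <- s > 0
  if (!any(ok))
    stopf("signature '%s' has only constant genes", label)
  z <- (sub[ok, , drop = FALSE] - mu[ok]) / s[ok]
  avg <- colMeans(z)
  s_avg <- sqrt(mean((avg - mean(avg))^2))
  if (s_avg == 0) return(rep(0, length(avg)))
  (avg - mean(avg)) / s_avg
}

#' Read a genes-of-interest file
#'
#' Plain-text format, one directive per line:
#' \preformatted{
#' gene CD8A
#' sum CD8 = CD8A + CD8B
#' minz SEN = [Cdkn1a, Cdkn2a] ; [Gfap, B2m]
#' }
#' Blank lines and lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return a [GOISpec-class]
#' @export
readGOISpec <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  targets <- lapply(lines, parse_goi_line)
  methods::new("GOISpec", targets = targets)
}

parse_goi_line <- function(line) {
  split1 <- regmatches(line, regexpr("^\\S+", line))
  rest <- trimws(sub("^\\S+\\s*", "", line))
  kind <- tolower(split1)
  if (kind == "gene") {
    return(list(name = rest, kind = "gene", genes = rest, signatures = NULL))
  }
  if (!grepl("=", rest)) stopf("malformed GOI directive: '%s'", line)
  name <- trimws(sub("=.*", "", rest))
  rhs <- trimws(sub("^[^=]*=", "", rest))
  if (kind == "sum") {
    genes <- trimws(strsplit(rhs, "\\+")[[1]])
    return(list(name = name, kind = "sum", genes = genes, signatures = NULL))
  }
  if (kind == "minz") {
    parts <- trimws(strsplit(rhs, ";")[[1]])
    sigs <- lapply(parts, function(p) {
      p <- gsub("^\\[|\\]$", "", p)
      trimws(strsplit(p, ",")[[1]])
    })
    names(sigs) <- paste0(name, "_sig", seq_along(sigs))
    return(list(name = name, kind = "min_signature_z", genes = character(),
                signatures = sigs))
  }
  stopf("unknown GOI directive kind '%s'", kind)
}

#' Write a genes-of-interest file
#' @param spec a [GOISpec-class]
#' @param path output file path
#' @export
writeGOISpec <- function(spec, path) {
  lines <- vapply(spec@targets, function(t) {
    switch(t$kind,
      gene = paste("gene", t$genes),
      sum  = sprintf("sum %s = %s", t$name, paste(t$genes, collapse = " + ")),
      min_signature_z = sprintf("minz %s = %s", t$name,
        paste(vapply(t$signatures, function(s)
          sprintf("[%s]", paste(s, collapse = ",")), ""), collapse = " ; ")))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
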