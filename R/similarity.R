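#' Between-sample distance matrix under the two study metrics
#'
#' Distances between sample expression profiles, computed on the raw
#' input columns (no scaling): plain Euclidean distance, or
#' `1 - Pearson correlation`, which ranks samples by shared expression
#' trends regardless of absolute level.
#'
#' @param em an [expr_matrix()] or matrix, genes x samples (typically
#'   log-TPM).
#' @param metric `"euclidean"` or `"one_minus_pearson"`.
#' @return symmetric matrix with zero diagonal; Pearson distances lie in
#'   `[0, 2]`.
#' @export
distance_matrix <- function(em, metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  x <- unclass(as.matrix(em))
  if (ncol(x) < 2) stopf("need at least two samples")
  if (metric == "euclidean") {
    d <- as.matrix(dist(t(x)))
  } else {
    v <- apply(x, 2, sd)
    if (any(v == 0))
      stopf("zero-variance sample(s) under pearson: %s",
            paste(colnames(x)[v == 0], collapse = ", "))
    d <- 1 - cor(x)
    d[abs(d) < 1e-15] <- 0
  }
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' UPGMA agglomeration over a distance matrix; ties between candidate
#' pairs break deterministically toward the lowest pair index.  Average
#' linkage is monotone, so merge heights are non-decreasing.
#'
#' @param d symmetric distance matrix with zero diagonal (sample ids as
#'   dimnames).
#' @return an `hclust` object.
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stopf("distance matrix must be symmetric")
  hclust(as.dist(d), method = "average")
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths follow the ultrametric interpretation of the merge
#' heights (leaf depth = merge height / 2), so cophenetic distances are
#' preserved.
#'
#' @param hc an `hclust` (e.g. from [average_linkage()]).
#' @param file optional path; when given, the text is also written
#'   there.
#' @return Newick string (invisibly when `file` is given).
#' @export
export_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Transcriptome similarity analysis under both metrics
#'
#' @param em expression matrix (log-TPM recommended, unscaled).
#' @return list with per-metric `dist` and `hclust` entries.
#' @export
similarity_analysis <- function(em) {
  lapply(setNames(nm = c("euclidean", "one_minus_pearson")), function(m) {
    d <- distance_matrix(em, m)
    list(dist = d, hclust = average_linkage(d))
  })
}
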