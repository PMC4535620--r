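#' Expression matrices with a recorded unit
#'
#' A numeric genes x samples matrix carrying its expression unit
#' (`"TPM"`, `"RPKM"`, `"log-TPM"`, `"log-RPKM"` or `"normalized-counts"`)
#' and, for log units, the pseudocount that was added.
#'
#' @param values numeric matrix with dimnames.
#' @param unit one of the units above.
#' @param pseudocount non-negative pseudocount used for log units.
#' @return an `expr_matrix`: a matrix with `unit`/`pseudocount` attributes.
#' @export
expr_matrix <- function(values, unit, pseudocount = NA_real_) {
  units <- c("TPM", "RPKM", "log-TPM", "log-RPKM", "normalized-counts")
  if (!unit %in% units) stopf("unknown unit '%s'", unit)
  values <- as.matrix(values)
  structure(values, unit = unit, pseudocount = pseudocount,
            class = c("expr_matrix", class(values)))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_unit <- function(x) attr(x, "unit")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              expr_unit(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM(g, s) = 1e9 * count(g, s) / (length(g) * colsum(s)).
#'
#' @param cm a [count_matrix()].
#' @return an [expr_matrix()] with unit `"RPKM"`.
#' @export
to_rpkm <- function(cm) {
  cs <- colSums(cm$counts)
  if (any(cs == 0))
    stopf("zero column sum for sample(s): %s",
          paste(colnames(cm$counts)[cs == 0], collapse = ", "))
  vals <- 1e9 * sweep(cm$counts / cm$lengths, 2, cs, "/")
  expr_matrix(vals, "RPKM")
}

#' Transcripts per million
#'
#' Length-normalized read rates rescaled so that every column sums to 1e6.
#'
#' @param cm a [count_matrix()].
#' @return an [expr_matrix()] with unit `"TPM"`.
#' @export
to_tpm <- function(cm) {
  cs <- colSums(cm$counts)
  if (any(cs == 0))
    stopf("zero column sum for sample(s): %s",
          paste(colnames(cm$counts)[cs == 0], collapse = ", "))
  rate <- cm$counts / cm$lengths
  vals <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expr_matrix(vals, "TPM")
}

#' Log10-transform an expression matrix
#'
#' @param em an [expr_matrix()] in a linear unit.
#' @param pseudocount non-negative value added before taking log10
#'   (default 1).
#' @return an [expr_matrix()] in the corresponding log unit.
#' @export
log_transform <- function(em, pseudocount = 1) {
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  unit <- expr_unit(em)
  if (startsWith(unit, "log-")) stopf("matrix is already on log scale")
  newunit <- if (unit %in% c("TPM", "RPKM")) paste0("log-", unit) else
    stopf("log_transform expects TPM or RPKM input")
  expr_matrix(log10(unclass(em) + pseudocount), newunit, pseudocount)
}

#' Median-of-ratios size factors
#'
#' Between-sample sequencing-depth factors in the DESeq convention: for
#' each gene expressed in every sample, take the ratio of its count to its
#' geometric mean across samples; the per-sample factor is the median of
#' these ratios.  Factors are rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix()].
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors_median_of_ratios <- function(cm) {
  counts <- cm$counts
  keep <- rowSums(counts == 0) == 0
  if (!any(keep))
    stopf(paste("no gene has nonzero counts in every sample;",
                "filter genes or samples before computing size factors"))
  lc <- log(counts[keep, , drop = FALSE])
  logref <- rowMeans(lc)
  f <- apply(lc, 2, function(x) exp(median(x - logref)))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Depth-normalized counts
#'
#' @param cm a [count_matrix()].
#' @param factors size factors; computed with
#'   [size_factors_median_of_ratios()] when missing.
#' @return an [expr_matrix()] with unit `"normalized-counts"`.
#' @export
normalized_counts <- function(cm, factors = NULL) {
  if (is.null(factors)) factors <- size_factors_median_of_ratios(cm)
  expr_matrix(sweep(cm$counts, 2, factors[colnames(cm$counts)], "/"),
              "normalized-counts")
}

#' Write / read an expression matrix as TSV with a unit header line
#'
#' @param em an [expr_matrix()].
#' @param file path.
#' @return `read_expr_matrix` returns an [expr_matrix()].
#' @export
write_expr_matrix <- function(em, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit=%s pseudocount=%s", expr_unit(em),
                     attr(em, "pseudocount")), con)
  tab <- data.frame(gene_id = rownames(em), unclass(em), check.names = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(file) {
  hdr <- readLines(file, n = 1)
  m <- regmatches(hdr, regexec("# unit=(\\S+) pseudocount=(\\S+)", hdr))[[1]]
  if (length(m) != 3) stopf("missing unit header line in %s", file)
  tab <- read.delim(file, skip = 1, check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab$gene_id
  expr_matrix(vals, m[2], suppressWarnings(as.numeric(m[3])))
}
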