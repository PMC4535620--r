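#' Gene-by-sample count matrix with gene lengths and sample metadata
#'
#' The central input container of the pipeline: an integer matrix of read
#' counts (genes in rows, samples in columns), per-gene lengths in bases,
#' and a sample sheet describing condition, replicate, temperature,
#' serotype label and parent condition.
#'
#' @param counts integer matrix, genes x samples, non-negative, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param lengths positive integer vector of gene lengths (bases), named by
#'   gene id or in row order of `counts`.
#' @param samples data.frame with one row per sample; must contain a
#'   `sample` column matching `colnames(counts)` and a `condition` column.
#'   Optional columns: `replicate`, `temperature`, `serotype`, `parent`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stopf("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and non-negative")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts) || any(!is.finite(lengths)) || any(lengths <= 0))
    stopf("lengths must be positive and match genes")
  names(lengths) <- rownames(counts)
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(counts),
                          condition = colnames(counts),
                          stringsAsFactors = FALSE)
  }
  if (!all(c("sample", "condition") %in% names(samples)))
    stopf("samples needs at least columns 'sample' and 'condition'")
  if (!setequal(samples$sample, colnames(counts)))
    stopf("sample sheet does not match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d conditions)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$condition))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Samples belonging to a condition
#' @param cm a [count_matrix()].
#' @param condition condition name.
#' @return character vector of sample ids.
#' @export
condition_samples <- function(cm, condition) {
  s <- cm$samples$sample[cm$samples$condition == condition]
  if (length(s) == 0) stopf("no samples for condition '%s'", condition)
  s
}

#' Write / read a count matrix as TSV plus sample sheet
#'
#' The counts table has columns `gene_id`, `length`, then one column per
#' sample. The sample sheet is a plain TSV of the metadata columns.
#'
#' @param cm a [count_matrix()].
#' @param counts_file,samples_file paths.
#' @return `write_count_matrix` returns the paths invisibly;
#'   `read_count_matrix` returns a [count_matrix()].
#' @export
write_count_matrix <- function(cm, counts_file, samples_file = NULL) {
  tab <- data.frame(gene_id = rownames(cm$counts),
                    length = as.integer(cm$lengths),
                    cm$counts, check.names = FALSE)
  write.table(tab, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_file))
    write.table(cm$samples, samples_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(counts_file, samples_file))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_file, samples_file = NULL) {
  tab <- read.delim(counts_file, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, setdiff(names(tab), c("gene_id", "length")), drop = FALSE])
  rownames(counts) <- tab$gene_id
  samples <- if (!is.null(samples_file))
    read.delim(samples_file, stringsAsFactors = FALSE) else NULL
  count_matrix(counts, setNames(tab$length, tab$gene_id), samples)
}
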