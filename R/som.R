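#' Self-organizing map configuration
#'
#' @param rows,cols lattice dimensions (default 20 x 20).
#' @param epochs full presentation passes over the genes (default 20).
#' @param lr_initial,lr_final learning-rate schedule (linear decay).
#' @param radius_initial,radius_final Gaussian neighbourhood radius
#'   schedule (linear decay); default initial is half the larger lattice
#'   side.
#' @param centering gene-wise mean-centering across samples before
#'   training (default TRUE).  Centering makes each landscape's MaxEXP
#'   positive and MinEXP negative in typical data, so that the
#'   0.9-extremum classification selects proper top and bottom bands.
#' @param seed RNG seed for codebook initialization and presentation
#'   order.
#' @return a `som_config` list.
#' @export
som_config <- function(rows = 20, cols = 20, epochs = 20,
                       lr_initial = 0.5, lr_final = 0.01,
                       radius_initial = max(rows, cols) / 2,
                       radius_final = 1, centering = TRUE, seed = 1) {
  stopifnot(rows * cols >= 4, epochs >= 1,
            lr_initial >= lr_final, lr_final > 0,
            radius_initial >= radius_final, radius_final > 0)
  structure(as.list(environment()), class = "som_config")
}

som_prepare <- function(em, centering) {
  x <- unclass(as.matrix(em))
  if (any(!is.finite(x))) stopf("SOM input contains non-finite values")
  if (ncol(x) < 2) stopf("SOM needs at least two samples")
  centers <- if (centering) rowMeans(x) else rep(0, nrow(x))
  list(x = x - centers, centers = setNames(centers, rownames(x)))
}

#' Train a self-organizing map on a gene expression matrix
#'
#' Genes are the observations (dimension = number of samples).  Online
#' Kohonen training with a Gaussian lattice neighbourhood, linear decay
#' of learning rate and radius, and codebook initialization from random
#' data rows; deterministic for a fixed seed.  Input is typically
#' log-TPM; with `centering = TRUE` (default) each gene is mean-centered
#' across samples first.
#'
#' @param em an [expr_matrix()] (or plain matrix), genes x samples.
#' @param cfg a [som_config()].
#' @return a `som_model`: `codebook` ((rows*cols) x samples, row-major
#'   over the lattice), `assignment` (gene -> unit index, ties to the
#'   lowest index), `qe` (mean quantization error; `qe_initial` records
#'   it for the untrained random-row codebook), `centers`, `data`
#'   (the training matrix after centering) and `config`.
#' @export
train_som <- function(em, cfg = som_config()) {
  prep <- som_prepare(em, cfg$centering)
  x <- prep$x
  m <- cfg$rows * cfg$cols
  if (nrow(x) < m)
    warnf("fewer genes (%d) than lattice units (%d)", nrow(x), m)
  set.seed(derive_seed(cfg$seed, 101))
  init_idx <- if (nrow(x) >= m) sample.int(nrow(x), m) else
    sample.int(nrow(x), m, replace = TRUE)
  codebook <- x[init_idx, , drop = FALSE]
  qe_initial <- attr(.som_assign_cpp(x, codebook + 0), "qe")
  order0 <- as.integer(unlist(lapply(seq_len(cfg$epochs), function(e)
    sample.int(nrow(x), nrow(x)))) - 1L)
  codebook <- .som_train_cpp(x, codebook + 0, cfg$rows, cfg$cols, order0,
                             cfg$lr_initial, cfg$lr_final,
                             cfg$radius_initial, cfg$radius_final)
  assignment <- .som_assign_cpp(x, codebook)
  qe <- attr(assignment, "qe")
  assignment <- setNames(as.integer(assignment), rownames(x))
  rownames(codebook) <- sprintf("u%03d", seq_len(m))
  colnames(codebook) <- colnames(x)
  structure(list(codebook = codebook, assignment = assignment, qe = qe,
                 qe_initial = qe_initial, centers = prep$centers, data = x,
                 config = cfg),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %dx%d lattice, %d genes, %d samples, qe=%.4f\n",
              x$config$rows, x$config$cols, length(x$assignment),
              ncol(x$codebook), x$qe))
  invisible(x)
}

#' Lattice coordinates of unit indices
#' @param units integer unit indices (row-major, 1-based).
#' @param cols number of lattice columns.
#' @return two-column matrix of (row, col).
#' @export
unit_coords <- function(units, cols) {
  cbind(row = (units - 1L) %/% cols + 1L, col = (units - 1L) %% cols + 1L)
}

#' Metagene expression landscape of one sample
#'
#' The landscape value of a lattice unit (its metagene expression
#' `Delta-e`) is the arithmetic mean, over the genes assigned to it, of
#' their expression in the given sample (on the training scale, i.e.
#' centered if the model was trained centered).  Units with no assigned
#' genes carry the codebook value and are flagged empty; they are
#' excluded from MaxEXP/MinEXP and from classification.
#'
#' @param model a `som_model`.
#' @param sample sample id (column of the training matrix).
#' @param em optional expression matrix to evaluate instead of the
#'   training data; the model's centering is applied to it.
#' @return a `som_landscape`: `sample`, `grid` (rows x cols matrix of
#'   `Delta-e`), `empty` (logical matrix), `n_genes` (counts per unit),
#'   `max_exp`, `min_exp` (extrema over non-empty units).
#' @export
landscape <- function(model, sample, em = NULL) {
  x <- if (is.null(em)) model$data else {
    xx <- unclass(as.matrix(em))
    xx - model$centers[rownames(xx)]
  }
  if (!sample %in% colnames(x)) stopf("unknown sample '%s'", sample)
  cfg <- model$config
  m <- cfg$rows * cfg$cols
  v <- x[names(model$assignment), sample]
  sums <- vapply(split(v, factor(model$assignment, levels = seq_len(m))),
                 sum, 0)
  n <- tabulate(model$assignment, nbins = m)
  de <- ifelse(n > 0, sums / pmax(n, 1), model$codebook[, sample])
  grid <- matrix(NA_real_, cfg$rows, cfg$cols)
  grid[cbind((seq_len(m) - 1L) %/% cfg$cols + 1L,
             (seq_len(m) - 1L) %% cfg$cols + 1L)] <- de
  empty <- matrix(TRUE, cfg$rows, cfg$cols)
  empty[unit_coords(which(n > 0), cfg$cols)] <- FALSE
  ngrid <- matrix(0L, cfg$rows, cfg$cols)
  ngrid[unit_coords(seq_len(m), cfg$cols)] <- n
  structure(list(sample = sample, grid = grid, empty = empty,
                 n_genes = ngrid,
                 max_exp = max(grid[!empty]), min_exp = min(grid[!empty])),
            class = "som_landscape")
}

#' Metagene (prototype) expression landscape of one sample
#'
#' The landscape of the trained metagene profiles themselves: unit
#' values are the codebook entries for the given sample.  Because the
#' neighbourhood training averages each prototype over many genes and
#' adjacent units, this field is the noise-damped version of the
#' member-mean landscape and is the default input for metagene
#' classification and spot detection: on the raw member means, the
#' multiplicative extremum band degenerates to the per-gene noise tail.
#'
#' @inheritParams landscape
#' @return a `som_landscape` (no unit is empty).
#' @export
metagene_landscape <- function(model, sample) {
  if (!sample %in% colnames(model$codebook)) stopf("unknown sample '%s'", sample)
  cfg <- model$config
  m <- cfg$rows * cfg$cols
  de <- model$codebook[, sample]
  grid <- matrix(NA_real_, cfg$rows, cfg$cols)
  grid[unit_coords(seq_len(m), cfg$cols)] <- de
  n <- tabulate(model$assignment, nbins = m)
  ngrid <- matrix(0L, cfg$rows, cfg$cols)
  ngrid[unit_coords(seq_len(m), cfg$cols)] <- n
  structure(list(sample = sample, grid = grid,
                 empty = matrix(FALSE, cfg$rows, cfg$cols),
                 n_genes = ngrid,
                 max_exp = max(grid), min_exp = min(grid)),
            class = "som_landscape")
}

#' Landscapes for all samples of a model
#' @param model a `som_model`.
#' @param samples sample ids (default: all training columns).
#' @param type `"member_mean"` (gene-level summary) or `"metagene"`
#'   (prototype field).
#' @return named list of `som_landscape` objects.
#' @export
landscapes <- function(model, samples = colnames(model$data),
                       type = c("member_mean", "metagene")) {
  type <- match.arg(type)
  fn <- if (type == "metagene") metagene_landscape else landscape
  setNames(lapply(samples, function(s) fn(model, s)), samples)
}
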