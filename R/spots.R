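#' Classify metagenes by the 0.9-extremum rule
#'
#' A metagene with landscape value `Delta-e` is classified over-expressed
#' iff `Delta-e > MaxEXP * factor` and under-expressed iff
#' `Delta-e < MinEXP * factor` (strict inequalities), where MaxEXP and
#' MinEXP are the extrema over the landscape's non-empty units (or
#' caller-supplied global extrema).  The rule selects proper top/bottom
#' bands only when `MaxEXP > 0` (over side) and `MinEXP < 0` (under
#' side); in other sign regimes the affected side is classified `none`
#' with a warning, and a constant landscape classifies everything
#' `none`.
#'
#' @param ls a `som_landscape`.
#' @param factor band factor, default 0.9.
#' @param max_exp,min_exp optional global extrema overriding the
#'   per-sample values.
#' @return character matrix (rows x cols) with values `"over"`,
#'   `"under"`, `"none"`; empty units are `"none"`.
#' @export
classify_metagenes <- function(ls, factor = 0.9, max_exp = NULL,
                               min_exp = NULL) {
  mx <- max_exp %||% ls$max_exp
  mn <- min_exp %||% ls$min_exp
  cls <- matrix("none", nrow(ls$grid), ncol(ls$grid))
  if (mx == mn) return(cls)
  if (mx > 0) {
    cls[!ls$empty & ls$grid > mx * factor] <- "over"
  } else {
    warnf("MaxEXP <= 0 in sample %s: over side ill-posed, none assigned",
          ls$sample)
  }
  if (mn < 0) {
    cls[!ls$empty & ls$grid < mn * factor] <- "under"
  } else {
    warnf("MinEXP >= 0 in sample %s: under side ill-posed, none assigned",
          ls$sample)
  }
  cls
}

#' Detect regulated spots as connected components of classified units
#'
#' A regulated spot is a maximal connected set of lattice units sharing
#' the same classification (`over` or `under`) in one sample's
#' landscape, under 4- or 8-neighbour adjacency.  Spots are ordered by
#' size (gene count, descending; empty model gives unit count), then by
#' their row-major anchor unit.
#'
#' @param cls classification matrix from [classify_metagenes()].
#' @param adjacency 4 or 8 (default 8).
#' @param model optional `som_model` used to attach member genes.
#' @param sample sample id recorded on the spots.
#' @return list of `regulated_spot` objects: `sample`, `class`, `units`
#'   (matrix of row/col), `genes`, `size`.
#' @export
detect_spots <- function(cls, adjacency = 8, model = NULL, sample = NA) {
  stopifnot(adjacency %in% c(4, 8))
  nr <- nrow(cls); nc <- ncol(cls)
  nb <- if (adjacency == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)) else
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  seen <- matrix(FALSE, nr, nc)
  spots <- list()
  for (klass in c("over", "under")) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (seen[i, j] || cls[i, j] != klass) next
      ## flood fill
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      comp <- matrix(integer(), 0, 2)
      while (length(stack)) {
        cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        comp <- rbind(comp, cur)
        for (k in seq_len(nrow(nb))) {
          ni <- cur[1] + nb[k, 1]; nj <- cur[2] + nb[k, 2]
          if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
          if (!seen[ni, nj] && cls[ni, nj] == klass) {
            seen[ni, nj] <- TRUE
            stack[[length(stack) + 1]] <- c(ni, nj)
          }
        }
      }
      colnames(comp) <- c("row", "col")
      genes <- character()
      if (!is.null(model)) {
        units <- (comp[, "row"] - 1L) * ncol(cls) + comp[, "col"]
        genes <- names(model$assignment)[model$assignment %in% units]
      }
      spots[[length(spots) + 1]] <- structure(
        list(sample = sample, class = klass, units = comp, genes = genes,
             size = if (is.null(model)) nrow(comp) else length(genes)),
        class = "regulated_spot")
    }
  }
  if (length(spots) == 0) return(spots)
  anchor <- vapply(spots, function(s)
    min((s$units[, "row"] - 1) * nc + s$units[, "col"]), numeric(1))
  sizes <- vapply(spots, function(s) s$size, 0)
  spots[order(-sizes, anchor)]
}

#' @export
print.regulated_spot <- function(x, ...) {
  cat(sprintf("regulated_spot [%s, %s]: %d units, %d genes\n",
              x$sample, x$class, nrow(x$units), length(x$genes)))
  invisible(x)
}

#' Detect spots for every sample of a model
#'
#' Convenience wrapper: builds each sample's landscape, classifies it
#' and extracts its spots.  By default classification runs on the
#' metagene (prototype) landscape, whose neighbourhood-averaged values
#' make the extremum band a stable spot selector; `source =
#' "member_mean"` classifies the raw per-unit gene means instead.
#'
#' @param model a `som_model`.
#' @param factor band factor for [classify_metagenes()].
#' @param adjacency 4 or 8.
#' @param global_extrema use extrema across all samples instead of
#'   per-sample MaxEXP/MinEXP (default FALSE).
#' @param samples sample ids (default: all).
#' @param source landscape type to classify: `"metagene"` (default) or
#'   `"member_mean"`.
#' @return named list (by sample) of spot lists.
#' @export
all_spots <- function(model, factor = 0.9, adjacency = 8,
                      global_extrema = FALSE,
                      samples = colnames(model$data),
                      source = c("metagene", "member_mean")) {
  source <- match.arg(source)
  lss <- landscapes(model, samples, type = source)
  mx <- mn <- NULL
  if (global_extrema) {
    mx <- max(vapply(lss, function(l) l$max_exp, 0))
    mn <- min(vapply(lss, function(l) l$min_exp, 0))
  }
  setNames(lapply(lss, function(ls) {
    cls <- classify_metagenes(ls, factor, max_exp = mx, min_exp = mn)
    detect_spots(cls, adjacency, model, ls$sample)
  }), samples)
}

#' Summarize spots across samples
#'
#' @param spot_sets named list (by sample) of spot lists, as returned by
#'   [all_spots()].
#' @return list with `table` (data.frame: sample, class, spot, n_units,
#'   n_genes) and `incidence` (binary gene x (sample.class) matrix of
#'   spot membership).
#' @export
spot_summary <- function(spot_sets) {
  rows <- list(); genes <- character()
  for (s in names(spot_sets)) for (sp in spot_sets[[s]]) {
    rows[[length(rows) + 1]] <- data.frame(
      sample = s, class = sp$class, spot = length(rows) + 1,
      n_units = nrow(sp$units), n_genes = length(sp$genes),
      stringsAsFactors = FALSE)
    genes <- union(genes, sp$genes)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), class = character(),
               spot = integer(), n_units = integer(), n_genes = integer())
  cols <- as.vector(t(outer(names(spot_sets), c("over", "under"),
                            paste, sep = ".")))
  inc <- matrix(0L, length(genes), length(cols),
                dimnames = list(sort(genes), cols))
  for (s in names(spot_sets)) for (sp in spot_sets[[s]])
    if (length(sp$genes))
      inc[sp$genes, paste(s, sp$class, sep = ".")] <- 1L
  list(table = tab, incidence = inc)
}
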