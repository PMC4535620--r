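#' Subtelomeric gene map
#'
#' Gene features with 1-based inclusive coordinates on scaffolds, plus
#' telomeric positions: scaffold ends (EOS) and internal telomeric
#' sites.
#'
#' @param scaffolds data.frame `scaffold`, `length`.
#' @param genes data.frame `gene`, `scaffold`, `start`, `end`, `strand`.
#' @param telomeres data.frame `scaffold`, `pos`, `type` with type in
#'   `EOS`/`internal`.
#' @return a `subtelomere_map`.
#' @export
subtelomere_map <- function(scaffolds, genes, telomeres) {
  stopifnot(all(genes$scaffold %in% scaffolds$scaffold),
            all(genes$start <= genes$end))
  lens <- setNames(scaffolds$length, scaffolds$scaffold)
  if (any(genes$start < 1) || any(genes$end > lens[genes$scaffold]))
    stopf("gene features outside scaffold bounds")
  telomeres <- telomeres[order(telomeres$scaffold, telomeres$pos), ]
  rownames(genes) <- rownames(telomeres) <- rownames(scaffolds) <- NULL
  structure(list(scaffolds = scaffolds, genes = genes,
                 telomeres = telomeres), class = "subtelomere_map")
}

#' @export
print.subtelomere_map <- function(x, ...) {
  cat(sprintf("subtelomere_map: %d scaffolds, %d genes, %d telomeric sites\n",
              nrow(x$scaffolds), nrow(x$genes), nrow(x$telomeres)))
  invisible(x)
}

#' Write / read a subtelomere map as GFF3
#'
#' Genes are `gene` features; internal telomeric sites are `telomere`
#' features; scaffold lengths travel in `##sequence-region` directives
#' (EOS positions are implicit as positions 1 and scaffold length).
#'
#' @param map a [subtelomere_map()].
#' @param file GFF3 path.
#' @return `read_subtelomere_gff` returns a [subtelomere_map()].
#' @export
write_subtelomere_gff <- function(map, file) {
  g <- map$genes
  it <- map$telomeres[map$telomeres$type == "internal", , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = c(g$scaffold, it$scaffold),
    ranges = IRanges::IRanges(start = c(g$start, it$pos),
                              end = c(g$end, it$pos)),
    strand = c(g$strand, rep("*", nrow(it))),
    type = c(rep("gene", nrow(g)), rep("telomere", nrow(it))),
    ID = c(g$gene, sprintf("telo_%03d", seq_len(nrow(it)))))
  sl <- setNames(map$scaffolds$length, map$scaffolds$scaffold)
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  rtracklayer::export.gff3(gr, file)
  ## scaffold lengths travel as sequence-region directives, which the
  ## exporter does not emit from seqinfo
  lines <- readLines(file)
  hdr_end <- which(!startsWith(lines, "##"))[1] - 1
  if (is.na(hdr_end)) hdr_end <- length(lines)
  directives <- sprintf("##sequence-region %s 1 %d", names(sl), sl)
  writeLines(c(lines[seq_len(hdr_end)], directives,
               lines[setdiff(seq_along(lines), seq_len(hdr_end))]), file)
  invisible(file)
}

#' @rdname write_subtelomere_gff
#' @export
read_subtelomere_gff <- function(file) {
  gr <- rtracklayer::import.gff3(file)
  ## scaffold lengths come from the sequence-region directives, which the
  ## importer does not surface in seqinfo
  dirs <- grep("^##sequence-region", readLines(file), value = TRUE)
  if (length(dirs) == 0)
    stopf("GFF3 lacks ##sequence-region directives for scaffold lengths")
  parts <- strsplit(trimws(dirs), "\\s+")
  sl <- setNames(as.numeric(vapply(parts, `[`, "", 4)),
                 vapply(parts, `[`, "", 2))
  miss <- setdiff(GenomeInfoDb::seqlevels(gr), names(sl))
  if (length(miss))
    stopf("GFF3 lacks ##sequence-region directives for scaffold lengths")
  scaffolds <- data.frame(scaffold = names(sl), length = unname(sl),
                          stringsAsFactors = FALSE)
  is_gene <- gr$type == "gene"
  gg <- gr[is_gene]
  genes <- data.frame(gene = gg$ID,
                      scaffold = as.character(GenomicRanges::seqnames(gg)),
                      start = GenomicRanges::start(gg),
                      end = GenomicRanges::end(gg),
                      strand = as.character(GenomicRanges::strand(gg)),
                      stringsAsFactors = FALSE)
  tt <- gr[gr$type == "telomere"]
  telo <- rbind(
    data.frame(scaffold = scaffolds$scaffold,
               pos = 1, type = "EOS", stringsAsFactors = FALSE),
    data.frame(scaffold = scaffolds$scaffold,
               pos = scaffolds$length, type = "EOS",
               stringsAsFactors = FALSE),
    data.frame(scaffold = as.character(GenomicRanges::seqnames(tt)),
               pos = GenomicRanges::start(tt),
               type = rep("internal", length(tt)),
               stringsAsFactors = FALSE))
  subtelomere_map(scaffolds, genes, telo)
}

#' Distance of a gene to the nearest telomeric position
#'
#' Distance in bp from the feature edge nearest the telomeric position,
#' minimized over the scaffold's EOS positions and (optionally) its
#' internal telomeric sites; the gene rank counts intervening genes
#' (0 = no gene between this gene and the telomere).
#'
#' @param map a [subtelomere_map()].
#' @param gene gene id.
#' @param include_internal also consider internal telomeric sites
#'   (default TRUE).
#' @return list `bp`, `rank`, `telomere_pos`.
#' @export
distance_to_telomere <- function(map, gene, include_internal = TRUE) {
  i <- match(gene, map$genes$gene)
  if (is.na(i)) stopf("gene '%s' not in map", gene)
  g <- map$genes[i, ]
  tl <- map$telomeres[map$telomeres$scaffold == g$scaffold, , drop = FALSE]
  if (!include_internal) tl <- tl[tl$type == "EOS", , drop = FALSE]
  ## bp distance from the nearest feature edge, 0 if the site overlaps
  d <- pmax(0, pmax(g$start - tl$pos, tl$pos - g$end))
  k <- which.min(d)
  tp <- tl$pos[k]
  sg <- map$genes[map$genes$scaffold == g$scaffold, ]
  lo <- min(g$end, tp); hi <- max(g$start, tp)
  between <- sg$gene != gene & sg$start > lo & sg$end < hi
  list(bp = d[k], rank = sum(between), telomere_pos = tp)
}

#' Expression profile of a focal gene's subtelomeric neighbourhood
#'
#' Orders the `k` genes up- and downstream of the focal gene along the
#' scaffold (offsets -k..+k, focal at 0) and tabulates their log10
#' expression per condition, along with each gene's distance to the
#' nearest telomeric position.
#'
#' @param map a [subtelomere_map()].
#' @param em expression matrix (linear TPM; logged internally with
#'   pseudocount 1).
#' @param cm optional [count_matrix()] for condition averaging; when
#'   NULL each column of `em` is one condition.
#' @param focal focal gene id.
#' @param k neighbours per side; truncated (and flagged) when the
#'   scaffold has fewer.
#' @return a `neighbour_profile`: data.frame with `gene`, `offset`,
#'   `bp_to_telomere`, `rank_to_telomere`, one column per condition;
#'   attribute `truncated`.
#' @export
neighbour_profile <- function(map, em, focal, k, cm = NULL) {
  stopifnot(k >= 1)
  i <- match(focal, map$genes$gene)
  if (is.na(i)) stopf("focal gene '%s' not in map", focal)
  sc <- map$genes$scaffold[i]
  sg <- map$genes[map$genes$scaffold == sc, ]
  sg <- sg[order(sg$start), ]
  pos <- match(focal, sg$gene)
  idx <- (pos - k):(pos + k)
  truncated <- any(idx < 1 | idx > nrow(sg))
  idx <- idx[idx >= 1 & idx <= nrow(sg)]
  genes <- sg$gene[idx]
  x <- log10(unclass(em)[genes, , drop = FALSE] + 1)
  if (!is.null(cm)) {
    conds <- unique(cm$samples$condition)
    x <- vapply(conds, function(cn)
      rowMeans(x[, condition_samples(cm, cn), drop = FALSE]),
      numeric(length(genes)))
    if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(genes, conds))
  }
  dt <- lapply(genes, function(g) distance_to_telomere(map, g))
  out <- data.frame(gene = genes, offset = idx - pos,
                    bp_to_telomere = vapply(dt, `[[`, 0, "bp"),
                    rank_to_telomere = vapply(dt, `[[`, 0L, "rank"),
                    stringsAsFactors = FALSE)
  expr_df <- as.data.frame(x, optional = TRUE)
  out <- data.frame(out, expr_df, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  if (truncated) warnf("fewer than k=%d neighbours on one side of %s", k, focal)
  class(out) <- c("neighbour_profile", "data.frame")
  out
}

#' Permutation test for heterochromatic spreading from the telomere
#'
#' For every focal SAg, the genes lying between it and its nearest
#' telomere are scored by the difference of mean log10 expression
#' between SAg-ON and SAg-OFF samples.  The test statistic is the
#' Spearman rank correlation, pooled over all focal scaffolds, between
#' this ON-OFF difference and proximity to the telomere (negative gene
#' rank).  Spreading silences OFF-state genes more strongly near the
#' telomere, producing a positive correlation; the one-sided p-value
#' comes from permuting the ON/OFF sample labels with a +1 correction,
#' so it is never exactly 0.
#'
#' @param map a [subtelomere_map()].
#' @param em expression matrix (linear scale; logged internally).
#' @param focal character vector of focal SAg gene ids.
#' @param on_samples,off_samples column names of `em` for SAg-ON and
#'   SAg-OFF states.
#' @param n_perm number of permutations (default 1000; below 100 warns).
#' @param seed RNG seed for the permutations.
#' @return list: `statistic`, `p`, `n_genes`, `per_gene` table.
#' @export
spreading_test <- function(map, em, focal, on_samples, off_samples,
                           n_perm = 1000, seed = 1) {
  if (n_perm < 100) warnf("n_perm < 100 gives a coarse p-value")
  x <- log10(unclass(em) + 1)
  rows <- list()
  for (f in focal) {
    ft <- distance_to_telomere(map, f)
    sc <- map$genes$scaffold[match(f, map$genes$gene)]
    sg <- map$genes[map$genes$scaffold == sc, ]
    fg <- sg[match(f, sg$gene), ]
    lo <- min(fg$end, ft$telomere_pos); hi <- max(fg$start, ft$telomere_pos)
    mid <- sg[sg$gene != f & sg$start > lo & sg$end < hi, ]
    if (nrow(mid) == 0) next
    rk <- vapply(mid$gene, function(g)
      distance_to_telomere(map, g)$rank, 0L)
    rows[[f]] <- data.frame(gene = mid$gene, focal = f, rank = rk,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stopf("no genes between any focal SAg and telomere")
  tab <- do.call(rbind, rows)
  labels <- c(on_samples, off_samples)
  is_on <- c(rep(TRUE, length(on_samples)), rep(FALSE, length(off_samples)))
  stat_fn <- function(onv) {
    d <- rowMeans(x[tab$gene, labels[onv], drop = FALSE]) -
      rowMeans(x[tab$gene, labels[!onv], drop = FALSE])
    if (all(abs(d) < 1e-12) || sd(d) == 0) return(0)
    suppressWarnings(cor(d, -tab$rank, method = "spearman"))
  }
  obs <- stat_fn(is_on)
  set.seed(derive_seed(seed, 71))
  perm <- vapply(seq_len(n_perm), function(i) stat_fn(sample(is_on)), 0)
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  d_obs <- rowMeans(x[tab$gene, on_samples, drop = FALSE]) -
    rowMeans(x[tab$gene, off_samples, drop = FALSE])
  tab$on_off_diff <- d_obs
  list(statistic = obs, p = p, n_genes = nrow(tab), per_gene = tab)
}
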