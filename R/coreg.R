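#' Active surface antigen of a condition
#'
#' The SAg family is mutually exclusive: one member dominates per
#' condition.  Returns the family member with the highest mean
#' expression over the condition's samples and its exclusivity ratio to
#' the runner-up; a ratio below 10 triggers a warning.
#'
#' @param em expression matrix (TPM recommended), genes x samples.
#' @param panel SAg family gene ids.
#' @param cm a [count_matrix()] supplying the sample sheet.
#' @param condition condition name.
#' @return list: `gene`, `ratio`, `means` (family means, sorted
#'   decreasing).
#' @export
active_sag <- function(em, panel, cm, condition) {
  if (length(panel) == 0) stopf("empty SAg panel")
  panel <- intersect(panel, rownames(em))
  if (length(panel) == 0) stopf("no panel gene found in matrix")
  smp <- condition_samples(cm, condition)
  mu <- sort(rowMeans(unclass(em)[panel, smp, drop = FALSE]),
             decreasing = TRUE)
  ratio <- if (length(mu) > 1) mu[1] / max(mu[2], .Machine$double.eps) else Inf
  if (is.finite(ratio) && ratio < 10)
    warnf("weak SAg exclusivity in %s: ratio %.2f", condition, ratio)
  list(gene = names(mu)[1], ratio = unname(ratio), means = mu)
}

#' The over-expressed spot containing the active SAg
#'
#' @param spots spot list of one sample (from [detect_spots()] /
#'   [all_spots()]).
#' @param sag active SAg gene id.
#' @return the matching `regulated_spot`, or `NULL` when the SAg is not
#'   member of any over-spot (a warning notes membership in an
#'   under-spot).
#' @export
sag_spot <- function(spots, sag) {
  for (sp in spots) {
    if (sag %in% sp$genes) {
      if (sp$class == "over") return(sp)
      warnf("SAg %s sits in an under-expressed spot", sag)
      return(NULL)
    }
  }
  NULL
}

#' Genes co-regulated with the active SAg
#'
#' A gene is co-regulated with the SAg when its spot-membership pattern
#' over all (sample, class) combinations equals the SAg's pattern: it
#' sits in an over (or under) spot in exactly the samples where the SAg
#' does.
#'
#' @param incidence binary gene x (sample.class) matrix from
#'   [spot_summary()].
#' @param sag active SAg gene id.
#' @return character vector of gene ids (always contains the SAg
#'   itself).
#' @export
coregulation_group <- function(incidence, sag) {
  if (!sag %in% rownames(incidence)) return(sag)
  ref <- incidence[sag, ]
  hit <- rownames(incidence)[colSums(t(incidence) != ref) == 0]
  union(sag, hit)
}

#' Persistence of a regulated spot in a derived condition
#'
#' Maximum Jaccard index between the parent spot's gene set and the gene
#' set of any over-spot of the derived sample.
#'
#' @param parent_spot a `regulated_spot` (or character vector of genes).
#' @param derived_spots spot list of the derived sample.
#' @return Jaccard index in `[0, 1]`.
#' @export
spot_persistence <- function(parent_spot, derived_spots) {
  genes <- if (inherits(parent_spot, "regulated_spot"))
    parent_spot$genes else parent_spot
  if (length(genes) == 0) stopf("empty parent spot")
  over <- Filter(function(s) s$class == "over", derived_spots)
  if (length(over) == 0) return(0)
  max(vapply(over, function(s) {
    length(intersect(genes, s$genes)) / length(union(genes, s$genes))
  }, 0))
}

#' Heat-shock contrast of HSP activation versus SAg decay
#'
#' Pairs replicates of the parent and heat-shocked condition by
#' replicate index and reports, per pair, the log2 fold change of each
#' cytosolic HSP panel gene and of the active SAg, plus the Spearman
#' rank correlation across replicate pairs between mean HSP activation
#' and SAg change (an inverse relation gives a negative value).
#'
#' @param em expression matrix (TPM recommended).
#' @param cm a [count_matrix()] supplying the sample sheet.
#' @param parent,hs condition names.
#' @param hsp_panel cytosolic HSP gene ids.
#' @param sag_panel SAg family gene ids.
#' @param pseudocount added before log2 ratios (default 1).
#' @return list: `table` (replicate, gene, class, lfc), `sag` (active
#'   SAg id), `correlation` (NA with a single replicate pair).
#' @export
heat_shock_contrast <- function(em, cm, parent, hs, hsp_panel, sag_panel,
                                pseudocount = 1) {
  x <- unclass(em)
  sag <- active_sag(em, sag_panel, cm, parent)$gene
  ps <- cm$samples[cm$samples$condition == parent, ]
  hss <- cm$samples[cm$samples$condition == hs, ]
  reps <- intersect(ps$replicate, hss$replicate)
  if (length(reps) < max(nrow(ps), nrow(hss)))
    warnf("unpaired replicates between %s and %s; pairing by index", parent, hs)
  rows <- list()
  for (r in reps) {
    a <- ps$sample[ps$replicate == r][1]
    b <- hss$sample[hss$replicate == r][1]
    for (g in c(hsp_panel, sag)) {
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, gene = g,
        class = if (g == sag) "SAg" else "HSP",
        lfc = log2((x[g, b] + pseudocount) / (x[g, a] + pseudocount)),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  corr <- NA_real_
  if (length(reps) >= 2) {
    hsp_m <- tapply(tab$lfc[tab$class == "HSP"],
                    tab$replicate[tab$class == "HSP"], mean)
    sag_m <- tapply(tab$lfc[tab$class == "SAg"],
                    tab$replicate[tab$class == "SAg"], mean)
    corr <- suppressWarnings(cor(hsp_m, sag_m[names(hsp_m)],
                                 method = "spearman"))
  } else {
    warnf("single replicate pair: HSP/SAg correlation undefined")
  }
  list(table = tab, sag = sag, correlation = unname(corr))
}

#' Serotype co-regulation report
#'
#' Per serotype-pure condition: the active SAg, its over-spot and the
#' exact-incidence co-regulation group; plus spot persistence from each
#' parent condition into its derived conditions and the heat-shock loss
#' fraction (share of parent-spot units no longer classified over in
#' the heat-shock landscape).
#'
#' @param model a trained `som_model`.
#' @param em TPM expression matrix (for active-SAg calls).
#' @param cm the [count_matrix()].
#' @param sag_panel SAg family gene ids.
#' @param factor,adjacency spot parameters.
#' @param replicate representative replicate used per condition
#'   (default 1).
#' @return a `coreg_report` list.
#' @export
coreg_report <- function(model, em, cm, sag_panel, factor = 0.9,
                         adjacency = 8, replicate = 1) {
  spot_sets <- all_spots(model, factor, adjacency)
  summ <- spot_summary(spot_sets)
  conds <- unique(cm$samples$condition)
  rep_sample <- function(cond) {
    s <- cm$samples
    s$sample[s$condition == cond & s$replicate == replicate][1]
  }
  per_cond <- list()
  for (cond in conds) {
    smp <- rep_sample(cond)
    act <- active_sag(em, sag_panel, cm, cond)
    sp <- sag_spot(spot_sets[[smp]], act$gene)
    per_cond[[cond]] <- list(
      sample = smp, active_sag = act$gene, exclusivity = act$ratio,
      spot = sp, spot_genes = if (is.null(sp)) 0L else length(sp$genes),
      coreg_group = coregulation_group(summ$incidence, act$gene))
  }
  ## persistence and unit-loss, parent -> derived
  pers <- list(); loss <- list()
  smeta <- unique(cm$samples[, c("condition", "parent")])
  for (i in seq_len(nrow(smeta))) {
    cond <- smeta$condition[i]; par <- smeta$parent[i]
    if (is.na(par) || is.null(per_cond[[par]]$spot)) next
    key <- paste(par, cond, sep = "->")
    dsmp <- rep_sample(cond)
    pers[[key]] <- spot_persistence(per_cond[[par]]$spot, spot_sets[[dsmp]])
    dcls <- classify_metagenes(metagene_landscape(model, dsmp), factor)
    pu <- per_cond[[par]]$spot$units
    loss[[key]] <- mean(dcls[pu] != "over")
  }
  structure(list(conditions = per_cond, persistence = unlist(pers),
                 unit_loss = unlist(loss),
                 spot_table = summ$table, incidence = summ$incidence),
            class = "coreg_report")
}
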