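#' Write a simulated dataset to a directory
#'
#' Emits the counts TSV, sample sheet, ground-truth JSON, annotation
#' GFF3 (genes plus internal telomeric sites, scaffold lengths as
#' sequence-region directives) and the GO OBO-lite / association files.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"),
             gff = file.path(dir, "annotation.gff3"),
             obo = file.path(dir, "go.obo"),
             assoc = file.path(dir, "gene2go.tsv"))
  write_count_matrix(sim$counts, paths["counts"], paths["samples"])
  truth <- sim$truth
  jsonlite::write_json(list(
    sag_active = as.list(truth$sag_active),
    module_members = truth$module_members,
    hsp_genes = truth$hsp_genes, sag_genes = truth$sag_genes,
    lib_factors = as.list(truth$lib_factors),
    go_planted_term = truth$go_planted_term,
    seed = truth$config$seed), paths["truth"], auto_unbox = TRUE,
    digits = NA)
  write_subtelomere_gff(sim$map, paths["gff"])
  write_go_data(sim$go, paths["obo"], paths["assoc"])
  invisible(paths)
}

#' Pipeline run configuration
#'
#' All stage parameters of the analysis with their standard defaults:
#' DE threshold FDR 0.01, a 20 x 20 SOM, spot band factor 0.9 with
#' 8-neighbour adjacency, both clustering metrics, GO reporting at
#' FDR 0.02.
#'
#' @param out_dir output directory.
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it.
#' @param simulate logical: generate data with [simulate_dataset()]
#'   (TRUE, default) or read `counts_file` / `samples_file`.
#' @param counts_file,samples_file input paths when `simulate = FALSE`.
#' @param sim a [sim_config()] used when simulating (its seed is
#'   overridden by the global seed).
#' @param stages character vector of stages to run, a subset of
#'   `c("de", "som", "coreg", "cluster", "tpe", "go")`.
#' @param de_fdr,som,spot_factor,adjacency,go_fdr,go_method,tpe_n_perm,log_pseudocount
#'   stage parameters.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, simulate = TRUE,
                       counts_file = NULL, samples_file = NULL,
                       sim = sim_config(),
                       stages = c("de", "som", "coreg", "cluster",
                                  "tpe", "go"),
                       de_fdr = 0.01, som = som_config(),
                       spot_factor = 0.9, adjacency = 8,
                       go_fdr = 0.02, go_method = "parent_child_union",
                       tpe_n_perm = 500, log_pseudocount = 1) {
  if (!simulate && (is.null(counts_file) || !file.exists(counts_file)))
    stopf("counts_file must exist when simulate = FALSE")
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param file YAML path with keys matching [run_config()] arguments
#'   (nested `sim:` and `som:` blocks are passed to [sim_config()] /
#'   [som_config()]).
#' @return a `run_config`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$som)) y$som <- do.call(som_config, y$som)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> normalize -> DE -> SOM -> spots -> coreg ->
#' clustering -> TPE scan -> GO enrichment in dependency order, writes
#' every stage output under `out_dir` and returns a manifest with
#' content hashes.  Reruns with the same configuration and seed
#' reproduce the hashes of all deterministic stages.
#'
#' @param cfg a [run_config()].
#' @return a `run_manifest` list: `files` (path -> md5), `summary`
#'   (per-stage key numbers), `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(); summary <- list()
  fail_stage <- function(stage, e)
    stopf("stage '%s' failed: %s (partial outputs kept in %s)",
          stage, conditionMessage(e), cfg$out_dir)

  ## data
  sim <- NULL
  if (cfg$simulate) {
    scfg <- cfg$sim; scfg$seed <- cfg$seed
    sim <- simulate_dataset(scfg)
    files <- c(files, unname(write_dataset(sim, file.path(cfg$out_dir, "data"))))
    cm <- sim$counts
    sag_panel <- sim$truth$sag_genes
    hsp_panel <- sim$truth$hsp_genes
    map <- sim$map; go <- sim$go
  } else {
    cm <- read_count_matrix(cfg$counts_file, cfg$samples_file)
    sag_panel <- grep("^SAG_", rownames(cm$counts), value = TRUE)
    hsp_panel <- grep("^HSP_", rownames(cm$counts), value = TRUE)
    map <- NULL; go <- NULL
  }
  summary$data <- list(n_genes = nrow(cm$counts),
                       n_samples = ncol(cm$counts))

  ## normalization
  factors <- size_factors_median_of_ratios(cm)
  tpm <- to_tpm(cm)
  ltpm <- log_transform(tpm, cfg$log_pseudocount)
  f <- file.path(cfg$out_dir, "log_tpm.tsv")
  write_expr_matrix(ltpm, f); files <- c(files, f)

  conds <- unique(cm$samples$condition)

  if ("de" %in% cfg$stages) tryCatch({
    fit <- estimate_dispersions(cm, factors)
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    de_counts <- list(); up_sets <- list(); down_sets <- list()
    for (pr in pairs) {
      res <- nb_wald_test(cm, pr[1], pr[2], factors, fit)
      dg <- call_degs(res, cfg$de_fdr)
      key <- paste(pr[1], pr[2], sep = "_vs_")
      f <- file.path(cfg$out_dir, paste0("de_", key, ".tsv"))
      write.table(dg$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
      de_counts[[key]] <- c(up = length(dg$up), down = length(dg$down))
      up_sets[[key]] <- dg$up; down_sets[[key]] <- dg$down
    }
    summary$de <- de_counts
  }, error = function(e) fail_stage("de", e))

  model <- NULL
  if ("som" %in% cfg$stages) tryCatch({
    scfg <- cfg$som; scfg$seed <- derive_seed(cfg$seed, 3)
    model <- train_som(ltpm, scfg)
    spot_sets <- all_spots(model, cfg$spot_factor, cfg$adjacency)
    summ <- spot_summary(spot_sets)
    f <- file.path(cfg$out_dir, "spots.tsv")
    write.table(summ$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    summary$som <- list(qe = model$qe, n_spots = nrow(summ$table))
  }, error = function(e) fail_stage("som", e))

  if ("coreg" %in% cfg$stages && !is.null(model)) tryCatch({
    rep_ <- coreg_report(model, tpm, cm, sag_panel, cfg$spot_factor,
                         cfg$adjacency)
    f <- file.path(cfg$out_dir, "coreg.json")
    jsonlite::write_json(list(
      active_sag = lapply(rep_$conditions, function(x)
        list(sag = x$active_sag, exclusivity = x$exclusivity,
             spot_genes = x$spot_genes,
             coreg_group_size = length(x$coreg_group))),
      persistence = as.list(rep_$persistence),
      unit_loss = as.list(rep_$unit_loss)), f, auto_unbox = TRUE,
      digits = NA)
    files <- c(files, f)
    summary$coreg <- list(persistence = rep_$persistence,
                          unit_loss = rep_$unit_loss)
    if (length(hsp_panel)) {
      hsrow <- cm$samples[cm$samples$temperature >= 39 &
                            !is.na(cm$samples$parent), ]
      if (nrow(hsrow)) {
        hsc <- heat_shock_contrast(tpm, cm, hsrow$parent[1],
                                   hsrow$condition[1], hsp_panel, sag_panel)
        summary$heat_shock <- list(correlation = hsc$correlation,
                                   mean_hsp_lfc = mean(hsc$table$lfc[
                                     hsc$table$class == "HSP"]),
                                   sag_lfc = mean(hsc$table$lfc[
                                     hsc$table$class == "SAg"]))
      }
    }
  }, error = function(e) fail_stage("coreg", e))

  if ("cluster" %in% cfg$stages) tryCatch({
    sim_res <- similarity_analysis(ltpm)
    for (m in names(sim_res)) {
      f <- file.path(cfg$out_dir, paste0("dendrogram_", m, ".nwk"))
      export_newick(sim_res[[m]]$hclust, f)
      files <- c(files, f)
    }
    summary$cluster <- lapply(sim_res, function(r)
      paste(r$hclust$labels[r$hclust$order], collapse = ","))
  }, error = function(e) fail_stage("cluster", e))

  if ("tpe" %in% cfg$stages && !is.null(map)) tryCatch({
    act <- vapply(conds, function(cn)
      active_sag(tpm, sag_panel, cm, cn)$gene, "")
    on_cond <- conds[1]
    focal <- act[[on_cond]]
    on_s <- condition_samples(cm, on_cond)
    off_s <- setdiff(colnames(cm$counts),
                     condition_samples(cm, on_cond))
    off_s <- off_s[!vapply(cm$samples$condition[match(off_s, cm$samples$sample)],
                           function(cn) act[[cn]] == focal, TRUE)]
    st <- spreading_test(map, tpm, focal, on_s, off_s,
                         n_perm = cfg$tpe_n_perm,
                         seed = derive_seed(cfg$seed, 5))
    summary$tpe <- list(focal = focal, statistic = st$statistic, p = st$p,
                        n_genes = st$n_genes)
  }, error = function(e) fail_stage("tpe", e))

  if ("go" %in% cfg$stages && !is.null(go) && "de" %in% cfg$stages)
    tryCatch({
      res_all <- list()
      for (key in names(up_sets)) {
        res <- enrich(go, up_sets[[key]], down_sets[[key]],
                      cfg$go_method, cfg$go_fdr)
        if (nrow(res)) res$contrast <- key
        res_all[[key]] <- res[res$p < 1, , drop = FALSE]
      }
      res <- do.call(rbind, res_all)
      f <- file.path(cfg$out_dir, "go_enrichment.tsv")
      write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
      nsig <- vapply(res_all, function(r) sum(r$significant), 0L)
      top <- res[res$significant, , drop = FALSE]
      top <- top[order(top$fdr), , drop = FALSE]
      summary$go <- list(n_significant = nsig[nsig > 0],
                         top_terms = unique(head(top$term, 5)))
    }, error = function(e) fail_stage("go", e))

  manifest <- structure(list(
    files = vapply(files, function(f) unname(tools::md5sum(f)), ""),
    summary = summary, config = cfg), class = "run_manifest")
  jsonlite::write_json(list(files = as.list(manifest$files),
                            summary = summary),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

#' Human-readable summary report of a pipeline run
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param file optional path to write the report to.
#' @return character vector of report lines, invisibly when written.
#' @export
write_report <- function(manifest, file = NULL) {
  s <- manifest$summary
  out <- c("serosom pipeline report", "=======================")
  if (!is.null(s$data))
    out <- c(out, sprintf("Data: %d genes x %d samples",
                          s$data$n_genes, s$data$n_samples))
  if (!is.null(s$de)) {
    out <- c(out, "", "Differential expression (up / down):")
    for (k in names(s$de))
      out <- c(out, sprintf("  %-22s %5d / %5d", k,
                            s$de[[k]]["up"], s$de[[k]]["down"]))
  }
  if (!is.null(s$som))
    out <- c(out, "", sprintf("SOM: quantization error %.4f, %d spots",
                              s$som$qe, s$som$n_spots))
  if (!is.null(s$coreg)) {
    out <- c(out, "", "Spot persistence (parent -> derived, Jaccard):")
    for (k in names(s$coreg$persistence))
      out <- c(out, sprintf("  %-18s %.3f", k, s$coreg$persistence[[k]]))
  }
  if (!is.null(s$heat_shock))
    out <- c(out, sprintf(
      "Heat shock: mean HSP lfc %+.2f, SAg lfc %+.2f, correlation %s",
      s$heat_shock$mean_hsp_lfc, s$heat_shock$sag_lfc,
      format(s$heat_shock$correlation, digits = 3)))
  if (!is.null(s$tpe))
    out <- c(out, sprintf("TPE spreading test (%s): stat %.3f, p %.4f",
                          s$tpe$focal, s$tpe$statistic, s$tpe$p))
  if (!is.null(s$go))
    out <- c(out, sprintf("GO: significant terms in %d contrast(s); top: %s",
                          length(s$go$n_significant),
                          paste(s$go$top_terms, collapse = ", ")))
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}
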