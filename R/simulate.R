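#' Default condition design for the synthetic generator
#'
#' Seven culture conditions, mirroring a serotype study design: three
#' long-term serotype-pure baselines (A.31, D.24, H.14), a serotype
#' variant selected out of D.24 (B.24), a cold-adapted derivative of B.24
#' (B.6), a starved derivative of D.24 (D.starv) and a 20-min 39 degree
#' heat-shock of D.24 (D.HS).  Each condition carries the serotype label
#' of its single active surface-antigen (SAg) gene and a condition
#' program (baseline, cold, starve or heatshock).
#'
#' @return data.frame with columns `name`, `temperature`, `serotype`,
#'   `parent`, `program`.
#' @export
default_conditions <- function() {
  data.frame(
    name        = c("A.31", "D.24", "H.14", "B.24", "B.6", "D.starv", "D.HS"),
    temperature = c(31, 24, 14, 24, 6, 24, 39),
    serotype    = c("51A", "51D", "51H", "51B", "51B", "51D", "51D"),
    parent      = c(NA, NA, NA, "D.24", "B.24", "D.24", "D.24"),
    program     = c("baseline", "baseline", "baseline", "baseline",
                    "cold", "starve", "heatshock"),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic serotype-transcriptome dataset
#'
#' Defines the statistical structure the pipeline assumes: negative
#' binomial counts (Var = mu + alpha * mu^2) with log-normal gene-wise
#' dispersion, log-normal baseline means, a mutually exclusive SAg family
#' with one dominant member per condition, planted co-regulated gene
#' modules that track the active SAg, condition programs, and unequal
#' library sizes.
#'
#' @param n_genes total number of genes (default 6000).
#' @param n_sag size of the SAg family (default 8).
#' @param conditions condition design data.frame, see
#'   [default_conditions()].
#' @param n_replicates replicates per condition (default 3).
#' @param module_sizes named integer vector, serotype -> planted
#'   co-regulated module size.
#' @param lfc_module log2 effect of module genes in conditions where their
#'   serotype is active (default 2).
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   gene-wise NB dispersion alpha.  The default median 0.005 reflects
#'   replicates that are aliquots of a single clonal culture.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of
#'   baseline mean counts of background genes.
#' @param module_meanlog,module_sdlog log-normal parameters of module-gene
#'   baseline means (drawn high-expressed).
#' @param sag_active_mean mean count of the active SAg in its condition.
#' @param sag_off_frac inactive SAg mean as a fraction of the active mean
#'   in the same condition (default 0.01, i.e. 100x exclusivity).
#' @param hs_sag_decay multiplicative decay of the SAg and its module
#'   under heat-shock (default 0.1).
#' @param hsp_activation fold activation of cytosolic HSP genes under
#'   heat-shock (default 32).
#' @param n_hsp number of cytosolic HSP genes (default 6).
#' @param perturb_frac fraction of background genes perturbed by cold /
#'   starvation programs (default 0.2).
#' @param perturb_sd sd of the normal log2 perturbation (default 1).
#' @param libsize_range range of uniform multiplicative library-size
#'   factors (default c(0.5, 2)).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 6000, n_sag = 8,
                       conditions = default_conditions(),
                       n_replicates = 3,
                       module_sizes = c("51A" = 500, "51B" = 500,
                                        "51D" = 500, "51H" = 500),
                       lfc_module = 2,
                       dispersion_meanlog = log(0.005),
                       dispersion_sdlog = 1,
                       baseline_meanlog = log(100), baseline_sdlog = 1.5,
                       module_meanlog = log(1000), module_sdlog = 0.5,
                       sag_active_mean = 5000, sag_off_frac = 0.01,
                       hs_sag_decay = 0.1, hsp_activation = 32, n_hsp = 6,
                       perturb_frac = 0.2, perturb_sd = 1,
                       libsize_range = c(0.5, 2), seed = 1) {
  module_sizes <- unlist(module_sizes)   # accept YAML-style named lists
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, n_sag >= 1, n_replicates >= 1,
            all(module_sizes >= 1), length(libsize_range) == 2)
  sero <- unique(conditions$serotype)
  fam <- sag_family_names(n_sag)
  if (!all(sero %in% fam))
    stopf("conditions use serotypes outside the %d-member SAg family", n_sag)
  if (!all(names(module_sizes) %in% fam))
    stopf("module_sizes names must be SAg serotypes")
  if (sum(module_sizes) + n_sag + n_hsp > n_genes)
    stopf("planted gene sets exceed n_genes")
  miss <- setdiff(conditions$parent[!is.na(conditions$parent)],
                  conditions$name)
  if (length(miss)) stopf("unknown parent condition(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(conditions$name)) stopf("duplicate condition names")
  structure(cfg, class = "sim_config")
}

sag_family_names <- function(n_sag) {
  base <- c("51A", "51B", "51C", "51D", "51E", "51G", "51H", "51J")
  if (n_sag <= length(base)) base[seq_len(n_sag)] else
    c(base, sprintf("51X%02d", seq_len(n_sag - length(base))))
}

#' Simulate a full serotype-transcriptome dataset with ground truth
#'
#' Draws a gene x sample negative binomial count matrix under the
#' configured condition design, together with the ground truth needed by
#' recovery tests, a subtelomeric gene layout and a small GO annotation
#' set with one planted enriched term.
#'
#' Counts for gene g in sample s are NB with mean
#' `mu(g, cond(s)) * libfactor(s)` and variance `mu + alpha_g * mu^2`.
#' Condition means are built as: baseline-program conditions draw fresh
#' baselines with their serotype's module ON (x 2^lfc_module) and their
#' SAg active; cold/starve conditions copy the parent and perturb a
#' fraction of background genes; the heat-shock condition copies the
#' parent, multiplies active SAg and module means by `hs_sag_decay` and
#' cytosolic HSP means by `hsp_activation`.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_dataset` with elements `counts`
#'   (a [count_matrix()]), `truth` (a `sim_truth` list), `map`
#'   (a `subtelomere_map`) and `go` (a `go_dataset` plus planted-term
#'   metadata).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 11))
  conds <- cfg$conditions

  fam <- sag_family_names(cfg$n_sag)
  sag_ids <- paste0("SAG_", fam)
  hsp_ids <- sprintf("HSP_CY%02d", seq_len(cfg$n_hsp))
  n_bg <- cfg$n_genes - cfg$n_sag - cfg$n_hsp
  bg_ids <- sprintf("PTET_%06d", seq_len(n_bg))
  genes <- c(sag_ids, hsp_ids, bg_ids)

  ## planted module members: disjoint samples of background genes
  pool <- sample(bg_ids)
  module_members <- list()
  off <- 0
  for (s in names(cfg$module_sizes)) {
    k <- cfg$module_sizes[[s]]
    if (off + k > length(pool)) stopf("module sizes exceed background genes")
    module_members[[s]] <- sort(pool[(off + 1):(off + k)])
    off <- off + k
  }
  if (anyDuplicated(unlist(module_members)))
    stopf("planted module gene sets overlap")

  ## baselines
  base_mean <- setNames(rlnorm(n_bg, cfg$baseline_meanlog, cfg$baseline_sdlog),
                        bg_ids)
  for (s in names(module_members))
    base_mean[module_members[[s]]] <-
      rlnorm(length(module_members[[s]]), cfg$module_meanlog, cfg$module_sdlog)
  hsp_base <- setNames(rlnorm(cfg$n_hsp, log(500), 0.3), hsp_ids)
  alpha <- setNames(rlnorm(cfg$n_genes, cfg$dispersion_meanlog,
                           cfg$dispersion_sdlog), genes)

  ## condition mean matrix (genes x conditions), pre library factor
  mu <- matrix(NA_real_, cfg$n_genes, nrow(conds),
               dimnames = list(genes, conds$name))
  sag_active <- setNames(paste0("SAG_", conds$serotype), conds$name)
  for (i in seq_len(nrow(conds))) {
    cn <- conds$name[i]; prog <- conds$program[i]
    if (prog == "baseline" || is.na(conds$parent[i])) {
      col <- c(setNames(rep(NA_real_, cfg$n_sag), sag_ids), hsp_base, base_mean)
      active <- conds$serotype[i]
      act_mean <- cfg$sag_active_mean
      col[sag_ids] <- act_mean * cfg$sag_off_frac
      col[paste0("SAG_", active)] <- act_mean
      if (active %in% names(module_members))
        col[module_members[[active]]] <-
          base_mean[module_members[[active]]] * 2^cfg$lfc_module
      mu[, cn] <- col[genes]
    } else {
      par <- conds$parent[i]
      if (!all(!is.na(mu[, par]))) stopf("parent '%s' must precede '%s'", par, cn)
      col <- mu[, par]
      names(col) <- genes
      if (prog %in% c("cold", "starve")) {
        free <- setdiff(bg_ids, unlist(module_members))
        hit <- sample(free, round(cfg$perturb_frac * length(free)))
        col[hit] <- col[hit] * 2^rnorm(length(hit), 0, cfg$perturb_sd)
      } else if (prog == "heatshock") {
        active <- conds$serotype[i]
        col[paste0("SAG_", active)] <- col[paste0("SAG_", active)] * cfg$hs_sag_decay
        if (active %in% names(module_members))
          col[module_members[[active]]] <-
            col[module_members[[active]]] * cfg$hs_sag_decay
        col[hsp_ids] <- col[hsp_ids] * cfg$hsp_activation
        ## keep family mutual exclusion under the decayed active level
        act <- col[paste0("SAG_", active)]
        inact <- setdiff(sag_ids, paste0("SAG_", active))
        col[inact] <- pmin(col[inact], act * cfg$sag_off_frac)
      } else stopf("unknown program '%s'", prog)
      mu[, cn] <- col
    }
  }

  ## samples, library factors, counts
  samples <- data.frame(
    sample = paste0(rep(conds$name, each = cfg$n_replicates), "-",
                    rep(seq_len(cfg$n_replicates), nrow(conds))),
    condition = rep(conds$name, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), nrow(conds)),
    temperature = rep(conds$temperature, each = cfg$n_replicates),
    serotype = rep(conds$serotype, each = cfg$n_replicates),
    parent = rep(conds$parent, each = cfg$n_replicates),
    stringsAsFactors = FALSE
  )
  lib <- setNames(runif(nrow(samples), cfg$libsize_range[1],
                        cfg$libsize_range[2]), samples$sample)
  mean_matrix <- mu[, samples$condition, drop = FALSE]
  colnames(mean_matrix) <- samples$sample
  mu_s <- sweep(mean_matrix, 2, lib, "*")
  counts <- matrix(rnbinom(length(mu_s), mu = mu_s,
                           size = 1 / alpha[rownames(mu_s)]),
                   nrow(mu_s), ncol(mu_s), dimnames = dimnames(mu_s))
  lengths <- setNames(pmax(200L, as.integer(round(
    rlnorm(cfg$n_genes, log(1500), 0.3)))), genes)
  ## SAg paralogs are near-identical in length; equal lengths also keep
  ## the family's mutual-exclusion ratio identical on count and TPM scale
  lengths[sag_ids] <- 2000L
  cm <- count_matrix(counts, lengths, samples)

  map <- build_subtelomere_map(genes, sag_ids, lengths,
                               seed = derive_seed(cfg$seed, 23))
  go <- simulate_go_data(genes, module_members,
                         seed = derive_seed(cfg$seed, 31))

  truth <- structure(list(
    sag_active = sag_active, module_members = module_members,
    hsp_genes = hsp_ids, sag_genes = sag_ids,
    cond_means = mu, mean_matrix = mean_matrix,
    alpha = alpha, lib_factors = lib, config = cfg,
    go_planted_term = go$planted_term), class = "sim_truth")
  structure(list(counts = cm, truth = truth, map = map, go = go$dataset),
            class = "sim_dataset")
}

#' True log2 fold changes between two conditions
#'
#' Recomputes the planted effect sizes from the noise-free condition mean
#' matrix; a gene is truly differential for the pair iff its value is
#' nonzero.
#'
#' @param truth `sim_truth` from [simulate_dataset()].
#' @param cond_a,cond_b condition names (log2 of B over A).
#' @return named numeric vector of log2 ratios.
#' @export
true_lfc <- function(truth, cond_a, cond_b) {
  stopifnot(inherits(truth, "sim_truth"))
  log2(truth$cond_means[, cond_b] / truth$cond_means[, cond_a])
}

#' Simulate an exchangeable two-group null count matrix
#'
#' Both groups share identical per-gene means; the only signal is NB
#' noise with the given dispersion.  Used for type-I-error and FDR
#' calibration of the differential-expression stage.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (two groups).
#' @param dispersion NB dispersion alpha: scalar or per-gene vector;
#'   0 gives Poisson counts.
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal parameters of the shared gene means.
#' @return a [count_matrix()] whose sample sheet labels the two groups
#'   `grpA` / `grpB`.
#' @export
simulate_null <- function(n_genes, n_per_group, dispersion, seed = 1,
                          meanlog = log(100), sdlog = 1.5) {
  if (n_genes < 1 || n_per_group < 1) stopf("non-positive dimensions")
  set.seed(derive_seed(seed, 43))
  genes <- sprintf("g%05d", seq_len(n_genes))
  mu <- rlnorm(n_genes, meanlog, sdlog)
  alpha <- rep_len(dispersion, n_genes)
  ns <- 2 * n_per_group
  mus <- matrix(mu, n_genes, ns)
  counts <- matrix(0, n_genes, ns)
  pois <- alpha == 0
  if (any(pois))
    counts[pois, ] <- rpois(sum(pois) * ns, mus[pois, ])
  if (any(!pois))
    counts[!pois, ] <- rnbinom(sum(!pois) * ns, mu = mus[!pois, ],
                               size = 1 / alpha[!pois])
  dimnames(counts) <- list(genes, paste0(rep(c("grpA", "grpB"),
                                             each = n_per_group), "-",
                                         seq_len(n_per_group)))
  samples <- data.frame(sample = colnames(counts),
                        condition = rep(c("grpA", "grpB"), each = n_per_group),
                        replicate = rep(seq_len(n_per_group), 2),
                        stringsAsFactors = FALSE)
  count_matrix(counts, setNames(rep(1000L, n_genes), genes), samples)
}

## ---- subtelomere layout used inside simulate_dataset -------------------

build_subtelomere_map <- function(genes, sag_ids, lengths, seed,
                                  n_neighb = 6, gap = 500) {
  set.seed(seed)
  other <- setdiff(genes, sag_ids)
  scaffolds <- list(); feats <- list(); telo <- list()
  used <- 0
  for (i in seq_along(sag_ids)) {
    ## layout: [upstream n_neighb genes] SAG [n_neighb genes] EOS(right)
    ids <- c(other[used + seq_len(n_neighb)], sag_ids[i],
             other[used + n_neighb + seq_len(n_neighb)])
    used <- used + 2 * n_neighb
    sc <- sprintf("scaffold_%03d", 100 + i)
    pos <- gap
    rows <- lapply(seq_along(ids), function(j) NULL)
    for (j in seq_along(ids)) {
      w <- lengths[[ids[j]]]
      rows[[j]] <- data.frame(gene = ids[j], scaffold = sc,
                              start = pos, end = pos + w - 1,
                              strand = sample(c("+", "-"), 1),
                              stringsAsFactors = FALSE)
      pos <- pos + w + gap
    }
    len <- pos
    scaffolds[[sc]] <- data.frame(scaffold = sc, length = len,
                                  stringsAsFactors = FALSE)
    feats[[sc]] <- do.call(rbind, rows)
    tl <- data.frame(scaffold = sc, pos = c(1, len),
                     type = "EOS", stringsAsFactors = FALSE)
    if (i %% 2 == 0) {
      ## internal telomeric site between upstream genes 2 and 3
      itp <- feats[[sc]]$end[2] + gap %/% 2
      tl <- rbind(tl, data.frame(scaffold = sc, pos = itp,
                                 type = "internal", stringsAsFactors = FALSE))
    }
    telo[[sc]] <- tl
  }
  ## remaining genes on large body scaffolds
  rest <- other[(used + 1):length(other)]
  n_body <- 20
  split_idx <- sort(rep_len(seq_len(n_body), length(rest)))
  for (b in seq_len(n_body)) {
    ids <- rest[split_idx == b]
    sc <- sprintf("scaffold_%03d", b)
    pos <- gap
    rows <- lapply(seq_along(ids), function(j) NULL)
    for (j in seq_along(ids)) {
      w <- lengths[[ids[j]]]
      rows[[j]] <- data.frame(gene = ids[j], scaffold = sc,
                              start = pos, end = pos + w - 1,
                              strand = sample(c("+", "-"), 1),
                              stringsAsFactors = FALSE)
      pos <- pos + w + gap
    }
    scaffolds[[sc]] <- data.frame(scaffold = sc, length = pos,
                                  stringsAsFactors = FALSE)
    feats[[sc]] <- do.call(rbind, rows)
    telo[[sc]] <- data.frame(scaffold = sc, pos = c(1, pos), type = "EOS",
                             stringsAsFactors = FALSE)
  }
  subtelomere_map(do.call(rbind, unname(scaffolds)),
                  do.call(rbind, unname(feats)),
                  do.call(rbind, unname(telo)))
}

## ---- GO generator ------------------------------------------------------

#' Simulate a small GO DAG and gene associations with one enriched term
#'
#' Builds a three-level is-a DAG (root, `n_parents` parents, `n_children`
#' leaf terms) and random gene-term associations, then plants one leaf
#' term whose annotated genes are drawn from a designated gene set (by
#' default the first planted module), so that enrichment of that set is
#' recoverable.
#'
#' @param genes character vector of gene ids (the population).
#' @param module_members list of planted gene sets; the first is used for
#'   the planted term (may be empty for a pure null DAG).
#' @param seed RNG seed.
#' @param n_parents,n_children DAG width (defaults 8 and 40).
#' @param planted_size genes annotated to the planted term (default 150).
#' @return list with `dataset` (a `go_dataset`) and `planted_term`.
#' @export
simulate_go_data <- function(genes, module_members = list(), seed = 1,
                             n_parents = 8, n_children = 40,
                             planted_size = 150) {
  set.seed(seed)
  root <- "GO:0000001"
  parents <- sprintf("GO:%07d", 10 + seq_len(n_parents))
  children <- sprintf("GO:%07d", 100 + seq_len(n_children))
  terms <- data.frame(
    id = c(root, parents, children),
    name = c("biological_process", paste0("process_", seq_len(n_parents)),
             paste0("subprocess_", seq_len(n_children))),
    stringsAsFactors = FALSE)
  is_a <- c(setNames(rep(list(character()), 1), root),
            setNames(rep(list(root), n_parents), parents),
            setNames(as.list(parents[1 + (seq_len(n_children) - 1) %% n_parents]),
                     children))
  ## random associations: every gene gets 1-3 leaf terms
  k <- sample(1:3, length(genes), replace = TRUE)
  ann <- data.frame(
    gene = rep(genes, k),
    term = unlist(lapply(k, function(m) sample(children, m))),
    stringsAsFactors = FALSE)
  planted <- NULL
  if (length(module_members) > 0 && length(module_members[[1]]) > 0) {
    planted <- children[1]
    pick <- sample(module_members[[1]],
                   min(planted_size, length(module_members[[1]])))
    ann <- ann[!(ann$term == planted), , drop = FALSE]
    ann <- rbind(ann, data.frame(gene = pick, term = planted,
                                 stringsAsFactors = FALSE))
  }
  list(dataset = go_dataset(terms, is_a, ann), planted_term = planted)
}

## ---- standalone subtelomere simulator ---------------------------------

#' Simulate subtelomeric scaffolds with an ON/OFF focal surface antigen
#'
#' Each synthetic scaffold carries a focal SAg with `genes_between`
#' neighbour genes between it and the right scaffold end (the telomere)
#' and `genes_upstream` genes on the other side.  Expression is drawn for
#' `n_on` samples with the SAg active and `n_off` samples with it
#' silent.  With `spreading = TRUE`, neighbour genes between the SAg and
#' the telomere are silenced in OFF samples with a factor `decay` per
#' gene step toward the telomere (the gene adjacent to the telomere is
#' most strongly silenced); with `spreading = FALSE` neighbour expression
#' is independent of SAg state and distance.
#'
#' @param n_scaffolds number of scaffolds (default 4).
#' @param genes_between genes between SAg and telomere (default 6).
#' @param genes_upstream genes on the far side of the SAg (default 6).
#' @param n_on,n_off samples with the SAg ON / OFF.  The defaults (3
#'   ON, 9 OFF) mirror the serotype study design: the focal SAg is
#'   active in one triplicate condition and silent in the three other
#'   serotype-pure triplicates.  An unbalanced design also gives the
#'   label-permutation null enough distinct splits for p-values below
#'   0.05.
#' @param spreading logical; plant heterochromatic spreading?
#' @param decay silencing factor per gene step toward the telomere
#'   (default 0.5).
#' @param noise_sd log10-scale sd of multiplicative expression noise
#'   (default 0.15).
#' @param seed RNG seed.
#' @return list of class `subtel_sim`: `map` (a `subtelomere_map`),
#'   `expr` (an [expr_matrix()] of TPM-like values), `focal` (SAg ids),
#'   `on_samples`, `off_samples`.
#' @export
simulate_subtelomere <- function(n_scaffolds = 4, genes_between = 6,
                                 genes_upstream = 6, n_on = 3, n_off = 9,
                                 spreading = FALSE, decay = 0.5,
                                 noise_sd = 0.15, seed = 1) {
  stopifnot(n_scaffolds >= 1, genes_between >= 1, n_on >= 1, n_off >= 1)
  set.seed(derive_seed(seed, 57))
  ## the SAg is subtelomeric: tight spacing toward the right scaffold end
  ## (its telomere), wide spacing on the chromosome-internal side, so the
  ## nearest telomeric position of the SAg and its downstream neighbours
  ## is always the downstream EOS
  gap_up <- 4000; gap_dn <- 300
  samples <- c(paste0("ON-", seq_len(n_on)), paste0("OFF-", seq_len(n_off)))
  on_samples <- samples[seq_len(n_on)]
  off_samples <- setdiff(samples, on_samples)
  feats <- list(); scaffolds <- list(); telo <- list()
  means <- list(); focal <- character()
  for (i in seq_len(n_scaffolds)) {
    sc <- sprintf("subtel_%02d", i)
    sag <- sprintf("SAGF_%02d", i)
    up <- sprintf("%s_u%02d", sc, seq_len(genes_upstream))
    dn <- sprintf("%s_d%02d", sc, seq_len(genes_between))
    ids <- c(up, sag, dn)   # left -> right; the SAg's telomere is the right EOS
    w <- as.integer(round(rlnorm(length(ids), log(1500), 0.2)))
    gaps <- c(rep(gap_up, genes_upstream + 1), rep(gap_dn, genes_between))
    pos <- gap_up
    rows <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      rows[[j]] <- data.frame(gene = ids[j], scaffold = sc, start = pos,
                              end = pos + w[j] - 1, strand = "+",
                              stringsAsFactors = FALSE)
      pos <- pos + w[j] + gaps[j]
    }
    feats[[sc]] <- do.call(rbind, rows)
    scaffolds[[sc]] <- data.frame(scaffold = sc, length = pos,
                                  stringsAsFactors = FALSE)
    telo[[sc]] <- data.frame(scaffold = sc, pos = c(1, pos), type = "EOS",
                             stringsAsFactors = FALSE)
    base <- setNames(rlnorm(length(ids), log(200), 0.4), ids)
    m <- matrix(base, length(ids), length(samples),
                dimnames = list(ids, samples))
    m[sag, on_samples] <- 2000
    m[sag, off_samples] <- 20
    if (spreading) {
      ## dn[j] lies j gene steps from the SAg toward the telomere; the
      ## heterochromatic factor compounds per step, strongest at the
      ## telomere-adjacent gene: decay^j
      sil <- decay^(seq_len(genes_between))
      m[dn, off_samples] <- m[dn, off_samples] * sil
    }
    means[[sc]] <- m
    focal <- c(focal, sag)
  }
  mu <- do.call(rbind, unname(means))
  expr <- matrix(rlnorm(length(mu), log(mu), noise_sd * log(10)),
                 nrow(mu), ncol(mu), dimnames = dimnames(mu))
  structure(list(
    map = subtelomere_map(do.call(rbind, unname(scaffolds)),
                          do.call(rbind, unname(feats)),
                          do.call(rbind, unname(telo))),
    expr = expr_matrix(expr, "TPM"),
    focal = focal, on_samples = on_samples, off_samples = off_samples,
    spreading = spreading, decay = decay), class = "subtel_sim")
}
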