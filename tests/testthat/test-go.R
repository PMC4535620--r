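flat_go <- function(n_terms = 6, genes = sprintf("g%02d", 1:40), seed = 80) {
  set.seed(seed)
  ids <- c("root", paste0("t", seq_len(n_terms)))
  terms <- data.frame(id = ids, name = ids, stringsAsFactors = FALSE)
  is_a <- c(list(root = character()),
            setNames(rep(list("root"), n_terms), ids[-1]))
  ann <- data.frame(gene = sample(genes, 120, replace = TRUE),
                    term = sample(ids[-1], 120, replace = TRUE))
  go_dataset(terms, is_a, unique(ann))
}

random_dag <- function(seed) {
  ## layered random DAG with cross links
  set.seed(seed)
  ids <- c("root", paste0("a", 1:3), paste0("b", 1:6))
  terms <- data.frame(id = ids, name = ids, stringsAsFactors = FALSE)
  is_a <- list(root = character())
  for (a in paste0("a", 1:3)) is_a[[a]] <- "root"
  for (b in paste0("b", 1:6))
    is_a[[b]] <- sample(paste0("a", 1:3), sample(1:2, 1))
  genes <- sprintf("g%02d", 1:60)
  ann <- unique(data.frame(
    gene = sample(genes, 150, replace = TRUE),
    term = sample(ids[-1], 150, replace = TRUE)))
  list(go = go_dataset(terms, is_a, ann), genes = genes)
}

test_that("DAG construction validates rootedness and acyclicity", {
  terms <- data.frame(id = c("r", "x", "y"), name = c("r", "x", "y"))
  expect_error(go_dataset(terms, list(r = character(), x = "y", y = "x"),
                          data.frame(gene = "g", term = "x")), "cycle")
  expect_error(go_dataset(terms, list(r = character(), x = character(),
                                      y = "x"),
                          data.frame(gene = "g", term = "x")), "root")
  expect_error(go_dataset(terms, list(r = character(), x = "r", y = "r"),
                          data.frame(gene = "g", term = "zzz")), "unknown")
})

test_that("annotation propagation is idempotent and monotone", {
  rd <- random_dag(81)
  go <- rd$go
  ## every ancestor of an annotated term carries the gene
  for (t in names(go$term_genes)) {
    for (p in go$parents[[t]])
      expect_true(all(go$term_genes[[t]] %in% go$term_genes[[p]]))
  }
  ## rebuilding from the propagated sets changes nothing
  ann2 <- data.frame(gene = unlist(go$term_genes),
                     term = rep(names(go$term_genes),
                                lengths(go$term_genes)))
  go2 <- go_dataset(go$terms, go$parents, ann2)
  expect_equal(go2$term_genes, go$term_genes)
  ## root covers the full population
  expect_setequal(go$term_genes[["root"]],
                  unique(unlist(go$term_genes)))
})

test_that("term-for-term p-values match the exact tail sum", {
  go <- flat_go()
  pop <- sort(names(go$gene_terms))
  expect_error(hypergeom_term_test(go, character(), "t1"), "empty")
  expect_error(hypergeom_term_test(go, c(pop[1], "alien"), "t1"), "subset")
  ## study = population gives p = 1 everywhere
  for (t in paste0("t", 1:6))
    expect_equal(hypergeom_term_test(go, pop, t), 1)

  ## literal 2x2 tail-sum oracle
  tail_sum <- function(k, K, N, n)
    sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), 0)) / choose(N, n)
  set.seed(82)
  for (i in 1:10) {
    t <- sample(paste0("t", 1:6), 1)
    study <- sample(pop, sample(5:15, 1))
    K <- length(go$term_genes[[t]])
    k <- length(intersect(study, go$term_genes[[t]]))
    expect_equal(hypergeom_term_test(go, study, t),
                 tail_sum(k, K, length(pop), length(study)),
                 tolerance = 1e-12)
  }
})

pcu_brute <- function(go, study, term) {
  ## independent literal implementation of the parent-child-union rule
  parents <- go$parents[[term]]
  if (length(parents) == 0) return(1)
  pu <- unique(unlist(lapply(parents, function(p) go$term_genes[[p]])))
  tg <- intersect(go$term_genes[[term]], pu)
  st <- intersect(study, pu)
  if (length(st) == 0) return(1)
  k <- length(intersect(st, tg))
  sum(vapply(k:min(length(tg), length(st)), function(i)
    choose(length(tg), i) *
      choose(length(pu) - length(tg), length(st) - i), 0)) /
    choose(length(pu), length(st))
}

test_that("parent-child-union reduces to term-for-term on flat DAGs", {
  go <- flat_go()
  pop <- sort(names(go$gene_terms))
  set.seed(83)
  study <- sample(pop, 12)
  for (t in paste0("t", 1:6))
    expect_equal(parent_child_union_test(go, study, t),
                 hypergeom_term_test(go, study, t), tolerance = 1e-12)
  expect_equal(parent_child_union_test(go, study, "root"), 1)
})

test_that("parent-child-union matches a brute-force oracle on random DAGs", {
  for (seed in 84:88) {
    rd <- random_dag(seed)
    go <- rd$go
    pop <- sort(names(go$gene_terms))
    set.seed(seed + 100)
    study <- sample(pop, min(15, length(pop)))
    for (t in go$terms$id)
      expect_equal(parent_child_union_test(go, study, t),
                   pcu_brute(go, study, t), tolerance = 1e-12)
  }
})

test_that("a term annotated identically to its single parent is unenriched", {
  terms <- data.frame(id = c("root", "p", "c"), name = c("root", "p", "c"))
  is_a <- list(root = character(), p = "root", c = "p")
  ann <- data.frame(gene = sprintf("g%02d", 1:10),
                    term = rep("c", 10))
  extra <- data.frame(gene = sprintf("h%02d", 1:20), term = "root")
  go <- go_dataset(terms, is_a, rbind(ann, extra))
  ## c and p carry identical gene sets -> no refinement, p = 1
  expect_equal(parent_child_union_test(go, sprintf("g%02d", 1:5), "c"), 1)
})

test_that("enrichment recovers the planted term and respects direction", {
  run <- demo_run(1)
  truth <- run$sim$truth
  go <- run$sim$go
  up <- truth$module_members[["51A"]]
  res <- enrich(go, up, character(0))
  top <- res[res$direction == "up", ][1, ]
  expect_equal(top$term, truth$go_planted_term)
  expect_lt(top$fdr, 0.05)
  expect_true(all(res$direction == "up"))

  ## empty inputs give an empty result frame
  e <- enrich(go, character(0), character(0))
  expect_equal(nrow(e), 0)
  expect_error(enrich(go, up, character(0), method = "bogus"))
})

test_that("null study sets are not systematically enriched", {
  run <- demo_run(1)
  go <- run$sim$go
  pop <- sort(names(go$gene_terms))
  set.seed(89)
  hits <- 0; total <- 0
  for (i in 1:20) {
    study <- sample(pop, 100)
    res <- enrich(go, study, character(0), "term_for_term")
    hits <- hits + sum(res$p < 0.05)
    total <- total + nrow(res)
  }
  expect_lt(hits / total, 0.12)
})

test_that("OBO-lite and association files round-trip", {
  rd <- random_dag(90)
  go <- rd$go
  obo <- tempfile(fileext = ".obo")
  assoc <- tempfile(fileext = ".tsv")
  write_go_data(go, obo, assoc)
  back <- read_go_data(obo, assoc)
  expect_setequal(back$terms$id, go$terms$id)
  nm <- sort(names(go$parents))
  expect_equal(lapply(back$parents[nm], sort), lapply(go$parents[nm], sort))
  expect_equal(back$term_genes[names(go$term_genes)], go$term_genes)

  ## part_of edges are accepted as is-a with a warning
  writeLines(c("[Term]", "id: root", "name: r", "",
               "[Term]", "id: c1", "name: c",
               "relationship: part_of root ! r"), obo)
  write.table(data.frame(gene = "g1", term = "c1"), assoc, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_warning(go2 <- read_go_data(obo, assoc), "part_of")
  expect_equal(go2$parents[["c1"]], "root")
})
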