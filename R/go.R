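#' GO DAG with propagated gene annotations
#'
#' A rooted acyclic is-a DAG plus gene-term associations.  On
#' construction, annotations are propagated to all ancestors, so a gene
#' annotated to a term is annotated to every term on the path to the
#' root (the propagation is idempotent and makes ancestor counts
#' monotone).
#'
#' @param terms data.frame with `id` and `name`.
#' @param is_a named list: term id -> character vector of parent ids
#'   (empty for the root).
#' @param annotations data.frame with `gene` and `term`.
#' @return a `go_dataset`: `terms`, `parents`, `ancestors`, `root`,
#'   `term_genes` (term -> propagated gene set), `gene_terms`.
#' @export
go_dataset <- function(terms, is_a, annotations) {
  ids <- terms$id
  parents <- setNames(vector("list", length(ids)), ids)
  for (t in ids) parents[[t]] <- intersect(is_a[[t]] %||% character(), ids)
  roots <- ids[lengths(parents) == 0]
  if (length(roots) != 1) stopf("DAG must have exactly one root, found %d",
                                length(roots))
  ## topological check + ancestor closure
  anc <- setNames(vector("list", length(ids)), ids)
  state <- setNames(integer(length(ids)), ids)  # 0 new, 1 visiting, 2 done
  visit <- function(t, chain) {
    if (state[[t]] == 1L) stopf("cycle in is-a links at %s", t)
    if (state[[t]] == 2L) return(anc[[t]])
    state[[t]] <<- 1L
    a <- character()
    for (p in parents[[t]]) a <- union(a, c(p, visit(p, c(chain, t))))
    anc[[t]] <<- a
    state[[t]] <<- 2L
    a
  }
  for (t in ids) visit(t, character())
  bad <- setdiff(annotations$term, ids)
  if (length(bad)) stopf("annotations reference unknown terms: %s",
                         paste(head(bad, 3), collapse = ", "))
  ## propagate
  term_genes <- setNames(lapply(ids, function(t) character()), ids)
  direct <- split(annotations$gene, annotations$term)
  for (t in names(direct)) {
    gs <- unique(direct[[t]])
    for (u in c(t, anc[[t]]))
      term_genes[[u]] <- union(term_genes[[u]], gs)
  }
  gene_terms <- split(rep(names(term_genes), lengths(term_genes)),
                      unlist(term_genes))
  structure(list(terms = terms, parents = parents, ancestors = anc,
                 root = roots, term_genes = lapply(term_genes, sort),
                 gene_terms = gene_terms), class = "go_dataset")
}

#' @export
print.go_dataset <- function(x, ...) {
  cat(sprintf("go_dataset: %d terms (root %s), %d annotated genes\n",
              nrow(x$terms), x$root, length(x$gene_terms)))
  invisible(x)
}

#' Read / write an OBO-lite ontology and a gene-association TSV
#'
#' The OBO-lite dialect covers `[Term]` stanzas with `id`, `name` and
#' `is_a` lines only; `relationship: part_of` lines are treated as is-a
#' with a warning.  The association file is a two-column TSV
#' (`gene`, `term`).
#'
#' @param obo_file,assoc_file paths.
#' @return a [go_dataset()].
#' @export
read_go_data <- function(obo_file, assoc_file) {
  lines <- readLines(obo_file)
  terms <- list(); is_a <- list()
  cur <- NULL; cur_name <- NA; cur_parents <- character()
  part_of_seen <- FALSE
  flush <- function() {
    if (!is.null(cur)) {
      terms[[length(terms) + 1]] <<- data.frame(id = cur, name = cur_name,
                                                stringsAsFactors = FALSE)
      is_a[[cur]] <<- cur_parents
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- NULL; cur_name <- NA
                          cur_parents <- character(); next }
    if (startsWith(ln, "id: ")) cur <- sub("^id: ", "", ln)
    else if (startsWith(ln, "name: ")) cur_name <- sub("^name: ", "", ln)
    else if (startsWith(ln, "is_a: "))
      cur_parents <- c(cur_parents,
                       sub(" !.*$", "", sub("^is_a: ", "", ln)))
    else if (grepl("^relationship: part_of ", ln)) {
      part_of_seen <- TRUE
      cur_parents <- c(cur_parents,
                       sub(" !.*$", "",
                           sub("^relationship: part_of ", "", ln)))
    }
  }
  flush()
  if (part_of_seen) warnf("part_of relationships treated as is-a")
  ann <- read.delim(assoc_file, header = TRUE, stringsAsFactors = FALSE)
  names(ann)[1:2] <- c("gene", "term")
  go_dataset(do.call(rbind, terms), is_a, ann)
}

#' @rdname read_go_data
#' @param go a [go_dataset()].
#' @param annotations original (unpropagated) associations to write; by
#'   default the propagated sets are written.
#' @export
write_go_data <- function(go, obo_file, assoc_file, annotations = NULL) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(go$terms))) {
    id <- go$terms$id[i]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", go$terms$name[i]),
             paste0("is_a: ", go$parents[[id]])[seq_along(go$parents[[id]])],
             "")
  }
  writeLines(out, obo_file)
  if (is.null(annotations))
    annotations <- data.frame(
      gene = unlist(go$term_genes),
      term = rep(names(go$term_genes), lengths(go$term_genes)),
      stringsAsFactors = FALSE)
  write.table(annotations, assoc_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(obo_file)
}

go_population <- function(go) sort(names(go$gene_terms))

#' Term-for-term hypergeometric enrichment p-value
#'
#' Upper-tail hypergeometric probability of observing at least the
#' study set's count of term-annotated genes, given the annotated
#' population.
#'
#' @param go a [go_dataset()].
#' @param study character vector of study gene ids (must be annotated,
#'   i.e. a subset of the population).
#' @param term term id.
#' @return p-value.
#' @export
hypergeom_term_test <- function(go, study, term) {
  pop <- go_population(go)
  if (length(study) == 0) stopf("empty study set")
  if (!all(study %in% pop)) stopf("study set is not a subset of the population")
  tg <- go$term_genes[[term]]
  k <- length(intersect(study, tg))
  phyper(k - 1, length(tg), length(pop) - length(tg), length(study),
         lower.tail = FALSE)
}

#' Parent-child-union enrichment p-value
#'
#' Hypergeometric test of the term's study count where the population
#' is restricted to genes annotated to the union of the term's parents,
#' and the study set is restricted likewise.  The root term (no
#' parents) gets p = 1.  On a flat DAG (all terms children of the
#' root), the parent union is the full population and the test reduces
#' to the term-for-term test.
#'
#' @inheritParams hypergeom_term_test
#' @return p-value.
#' @export
parent_child_union_test <- function(go, study, term) {
  pop <- go_population(go)
  if (length(study) == 0) stopf("empty study set")
  if (!all(study %in% pop)) stopf("study set is not a subset of the population")
  parents <- go$parents[[term]]
  if (length(parents) == 0) return(1)
  pu <- sort(unique(unlist(go$term_genes[parents])))
  tg <- intersect(go$term_genes[[term]], pu)
  st <- intersect(study, pu)
  if (length(st) == 0) return(1)
  k <- length(intersect(st, tg))
  phyper(k - 1, length(tg), length(pu) - length(tg), length(st),
         lower.tail = FALSE)
}

#' GO enrichment of up- and down-regulated gene sets
#'
#' Tests every annotated non-root term for enrichment in each direction
#' with the chosen method and applies Benjamini--Hochberg correction
#' across terms within a direction.  Genes without annotation are
#' dropped from the study sets.
#'
#' @param go a [go_dataset()].
#' @param up,down character vectors of differential gene ids.
#' @param method `"parent_child_union"` (default) or `"term_for_term"`.
#' @param fdr reporting threshold on adjusted values (default 0.02).
#' @return data.frame: `term`, `name`, `direction`, `study_count`,
#'   `pop_count`, `p`, `fdr`, `significant`, `method`.
#' @export
enrich <- function(go, up, down, method = c("parent_child_union",
                                            "term_for_term"),
                   fdr = 0.02) {
  method <- match.arg(method)
  pop <- go_population(go)
  testf <- if (method == "parent_child_union") parent_child_union_test else
    hypergeom_term_test
  terms <- setdiff(go$terms$id, go$root)
  terms <- terms[lengths(go$term_genes[terms]) > 0]
  one_dir <- function(set, dir) {
    set <- intersect(set, pop)
    if (length(set) == 0 || length(terms) == 0)
      return(NULL)
    p <- vapply(terms, function(t) testf(go, set, t), 0)
    data.frame(term = terms,
               name = go$terms$name[match(terms, go$terms$id)],
               direction = dir,
               study_count = vapply(terms, function(t)
                 length(intersect(set, go$term_genes[[t]])), 0L),
               pop_count = lengths(go$term_genes[terms]),
               p = p, fdr = bh_adjust(p), stringsAsFactors = FALSE,
               row.names = NULL)
  }
  res <- rbind(one_dir(up, "up"), one_dir(down, "down"))
  if (is.null(res))
    return(data.frame(term = character(), name = character(),
                      direction = character(), study_count = integer(),
                      pop_count = integer(), p = numeric(),
                      fdr = numeric(), significant = logical(),
                      method = character()))
  res$significant <- res$fdr <= fdr
  res$method <- method
  res[order(res$direction, res$p), ]
}
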