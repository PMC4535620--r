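# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Full default-design simulation plus trained SOM for a given seed.
demo_run <- function(seed = 1) {
  memo(paste0("run", seed), {
    sim <- simulate_dataset(sim_config(seed = seed))
    tpm <- to_tpm(sim$counts)
    ltpm <- log_transform(tpm)
    model <- train_som(ltpm, som_config(seed = seed))
    list(sim = sim, tpm = tpm, ltpm = ltpm, model = model,
         spots = all_spots(model))
  })
}

# Small count matrix with two groups for unit tests.
tiny_counts <- function(n_genes = 50, n_per_group = 3, seed = 99,
                        mu = 100, alpha = 0.1) {
  set.seed(seed)
  counts <- matrix(rnbinom(n_genes * 2 * n_per_group, mu = mu,
                           size = 1 / alpha),
                   n_genes, 2 * n_per_group)
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  colnames(counts) <- paste0(rep(c("a", "b"), each = n_per_group),
                             seq_len(n_per_group))
  count_matrix(counts, setNames(rep(1000, n_genes), rownames(counts)),
               data.frame(sample = colnames(counts),
                          condition = rep(c("A", "B"), each = n_per_group),
                          replicate = rep(seq_len(n_per_group), 2)))
}

# Hand-built som_model for landscape oracles: arbitrary assignment over a
# small lattice.
toy_model <- function(x, rows, cols, assignment) {
  m <- rows * cols
  codebook <- matrix(0, m, ncol(x), dimnames = list(NULL, colnames(x)))
  for (u in seq_len(m)) {
    idx <- which(assignment == u)
    if (length(idx)) codebook[u, ] <- colMeans(x[idx, , drop = FALSE])
  }
  structure(list(codebook = codebook,
                 assignment = setNames(assignment, rownames(x)),
                 qe = NA_real_, centers = setNames(rep(0, nrow(x)),
                                                   rownames(x)),
                 data = x,
                 config = som_config(rows = rows, cols = cols)),
            class = "som_model")
}

# Wrap a plain numeric grid as a som_landscape (for classification tests).
toy_landscape <- function(grid, sample = "s1") {
  structure(list(sample = sample, grid = grid,
                 empty = matrix(FALSE, nrow(grid), ncol(grid)),
                 n_genes = matrix(1L, nrow(grid), ncol(grid)),
                 max_exp = max(grid), min_exp = min(grid)),
            class = "som_landscape")
}

# Independent connected-components oracle built on igraph.
spots_oracle <- function(cls, adjacency) {
  nr <- nrow(cls); nc <- ncol(cls)
  out <- list()
  for (klass in c("over", "under")) {
    cells <- which(cls == klass, arr.ind = TRUE)
    if (nrow(cells) == 0) next
    key <- paste(cells[, 1], cells[, 2])
    edges <- character(0)
    offs <- if (adjacency == 4) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)) else
      cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
    for (i in seq_len(nrow(cells))) for (k in seq_len(nrow(offs))) {
      p <- cells[i, ] + offs[k, ]
      pk <- paste(p[1], p[2])
      if (pk %in% key) edges <- c(edges, key[i], pk)
    }
    g <- igraph::graph_from_data_frame(
      if (length(edges)) matrix(edges, ncol = 2, byrow = TRUE) else
        matrix(character(), ncol = 2),
      directed = FALSE, vertices = data.frame(name = key))
    comp <- igraph::components(g)$membership
    out[[klass]] <- unname(split(names(comp), comp))
  }
  out
}

# Canonical form of spots for comparison with the oracle.
spots_canonical <- function(spots, klass) {
  got <- lapply(Filter(function(s) s$class == klass, spots), function(s)
    sort(paste(s$units[, "row"], s$units[, "col"])))
  got[order(vapply(got, `[`, "", 1))]
}
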