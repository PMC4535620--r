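test_that("BH adjustment matches its closed form, p.adjust and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  bh_brute <- function(p) {
    ## O(m^2) literal step-up definition
    m <- length(p)
    o <- order(p)
    vapply(seq_len(m), function(i) {
      rank_i <- which(o == i)
      min(vapply(rank_i:m, function(j) min(p[o[j]] * m / j, 1), 0))
    }, 0)
  }
  set.seed(20)
  for (i in 1:10) {
    p <- runif(sample(5:60, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  ## ties
  p <- c(0.1, 0.1, 0.05, 0.05, 1)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})

test_that("dispersion estimation recovers known regimes", {
  ## constant counts: raw dispersion exactly zero
  counts <- matrix(50L, 20, 6,
                   dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  cm <- count_matrix(counts, setNames(rep(1000, 20), rownames(counts)),
                     data.frame(sample = colnames(counts),
                                condition = rep(c("A", "B"), each = 3)))
  fit <- estimate_dispersions(cm, setNames(rep(1, 6), colnames(counts)))
  expect_equal(unname(fit$alpha_raw), rep(0, 20))

  ## Poisson counts: median raw dispersion near zero
  set.seed(21)
  pois <- matrix(rpois(3000 * 6, 200), 3000, 6,
                 dimnames = list(sprintf("g%04d", 1:3000), paste0("s", 1:6)))
  cmp <- count_matrix(pois, setNames(rep(1000, 3000), rownames(pois)),
                      data.frame(sample = colnames(pois),
                                 condition = rep(c("A", "B"), each = 3)))
  fitp <- estimate_dispersions(cmp, setNames(rep(1, 6), colnames(pois)))
  expect_lt(median(fitp$alpha_raw), 0.005)

  ## NB at alpha 0.2, mu 500, 50 replicates per group: within 20%
  set.seed(22)
  nb <- matrix(rnbinom(2000 * 100, mu = 500, size = 5), 2000, 100,
               dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:100)))
  cmn <- count_matrix(nb, setNames(rep(1000, 2000), rownames(nb)),
                      data.frame(sample = colnames(nb),
                                 condition = rep(c("A", "B"), each = 50)))
  fitn <- estimate_dispersions(cmn, setNames(rep(1, 100), colnames(nb)))
  expect_lt(abs(median(fitn$alpha) / 0.2 - 1), 0.2)

  ## single-replicate group is rejected
  cm1 <- count_matrix(counts[, 1:3],
                      setNames(rep(1000, 20), rownames(counts)),
                      data.frame(sample = colnames(counts)[1:3],
                                 condition = c("A", "A", "B")))
  expect_error(estimate_dispersions(cm1, setNames(rep(1, 3),
                                                  colnames(counts)[1:3])),
               "replicates")
})

test_that("identical groups give exactly zero fold changes", {
  cm0 <- tiny_counts()
  counts <- cm0$counts[, c(1:3, 1:3)]
  colnames(counts) <- paste0("s", 1:6)
  cm <- count_matrix(counts, cm0$lengths,
                     data.frame(sample = colnames(counts),
                                condition = rep(c("A", "B"), each = 3)))
  res <- nb_wald_test(cm, "A", "B",
                      factors = setNames(rep(1, 6), colnames(counts)))
  expect_equal(res$log2FC, rep(0, nrow(res)))
  expect_equal(res$p, rep(1, nrow(res)))
})

test_that("group-label swap negates fold changes and keeps p-values", {
  cm <- tiny_counts(seed = 30)
  f <- setNames(rep(1, 6), colnames(cm$counts))
  ab <- nb_wald_test(cm, "A", "B", f)
  ba <- nb_wald_test(cm, "B", "A", f)
  expect_equal(ab$log2FC, -ba$log2FC)
  expect_equal(ab$p, ba$p)
})

test_that("results are invariant to depth rescaling absorbed by factors", {
  cm <- tiny_counts(seed = 31)
  f1 <- setNames(rep(1, 6), colnames(cm$counts))
  res1 <- nb_wald_test(cm, "A", "B", f1)
  counts2 <- cm$counts
  counts2[, 2] <- counts2[, 2] * 4L
  cm2 <- count_matrix(counts2, cm$lengths, cm$samples)
  f2 <- f1; f2[2] <- 4
  res2 <- nb_wald_test(cm2, "A", "B", f2)
  ## normalized means and fold changes are exactly invariant; the NB
  ## variance keeps a per-sample shot-noise term q/f, so p-values move
  ## only marginally with the rescaled depth
  expect_equal(res1$log2FC, res2$log2FC, tolerance = 1e-12)
  expect_equal(res1$baseMean, res2$baseMean, tolerance = 1e-12)
  expect_equal(res1$p, res2$p, tolerance = 0.05)
})

test_that("planted log2 fold changes of 2 are recovered within 0.3", {
  set.seed(32)
  n <- 2000; n_de <- 200
  mu <- rlnorm(n, log(300), 1)
  mu <- pmax(mu, 100)
  alpha <- pmin(rlnorm(n, log(0.05), 0.7), 0.2)
  muB <- mu
  de_idx <- seq_len(n_de)
  muB[de_idx] <- mu[de_idx] * 4
  counts <- cbind(
    matrix(rnbinom(n * 3, mu = mu, size = 1 / alpha), n, 3),
    matrix(rnbinom(n * 3, mu = muB, size = 1 / alpha), n, 3))
  dimnames(counts) <- list(sprintf("g%04d", 1:n), paste0("s", 1:6))
  cm <- count_matrix(counts, setNames(rep(1000, n), rownames(counts)),
                     data.frame(sample = colnames(counts),
                                condition = rep(c("A", "B"), each = 3)))
  res <- nb_wald_test(cm, "A", "B")
  expect_lt(abs(median(res$log2FC[de_idx]) - 2), 0.3)
  dg <- call_degs(res, 0.01)
  ## most planted genes are called, few nulls are
  expect_gt(length(intersect(dg$up, rownames(counts)[de_idx])) / n_de, 0.7)
})

test_that("all-zero genes are flagged with p = 1", {
  cm0 <- tiny_counts(seed = 33)
  counts <- rbind(cm0$counts, zz = 0L)
  cm <- count_matrix(counts, setNames(rep(1000, nrow(counts)),
                                      rownames(counts)), cm0$samples)
  res <- nb_wald_test(cm, "A", "B",
                      setNames(rep(1, 6), colnames(counts)))
  zz <- res[res$gene == "zz", ]
  expect_true(zz$all_zero)
  expect_equal(zz$p, 1)
  expect_equal(zz$log2FC, 0)
})

test_that("DEG calling partitions significant genes by sign", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2FC = c(2, -2, 1, -1),
                    fdr = c(0.001, 0.005, 0.5, 0.2))
  dg <- call_degs(res, 0.01)
  expect_equal(dg$up, "a")
  expect_equal(dg$down, "b")
  empty <- call_degs(res[res$fdr > 0.1, ], 0.01)
  expect_equal(length(empty$up) + length(empty$down), 0)
})

test_that("fold-change estimates agree with DESeq2 on a shared fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(34)
  n <- 300
  mu <- rlnorm(n, log(200), 1)
  muB <- mu * 2^sample(c(0, 2, -2), n, replace = TRUE, prob = c(.8, .1, .1))
  counts <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 20), n, 3),
                  matrix(rnbinom(n * 3, mu = muB, size = 20), n, 3))
  dimnames(counts) <- list(sprintf("g%03d", 1:n), paste0("s", 1:6))
  cond <- rep(c("A", "B"), each = 3)
  cm <- count_matrix(counts, setNames(rep(1000, n), rownames(counts)),
                     data.frame(sample = colnames(counts), condition = cond))
  res <- nb_wald_test(cm, "A", "B")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, data.frame(condition = factor(cond, c("A", "B"))), ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  dres <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  expect_gt(cor(res$log2FC, dres$log2FoldChange, use = "complete.obs"), 0.95)
  ## strong calls overlap
  ours <- res$gene[res$fdr < 0.01]
  theirs <- rownames(dres)[!is.na(dres$padj) & dres$padj < 0.01]
  expect_gt(length(intersect(ours, theirs)) /
              max(1, length(union(ours, theirs))), 0.5)
})
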