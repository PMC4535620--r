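test_that("training is deterministic and maps duplicates together", {
  set.seed(40)
  x <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  cfg <- som_config(rows = 5, cols = 5, epochs = 5, seed = 9)
  m1 <- train_som(x, cfg)
  m2 <- train_som(x, cfg)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$assignment, m2$assignment)

  ## duplicated observations share a best-matching unit
  xdup <- rbind(x, x[1:10, ])
  rownames(xdup) <- c(rownames(x), sprintf("dup%02d", 1:10))
  md <- train_som(xdup, cfg)
  expect_equal(unname(md$assignment[sprintf("dup%02d", 1:10)]),
               unname(md$assignment[rownames(x)[1:10]]))
})

test_that("well-separated clouds occupy disjoint lattice regions", {
  set.seed(41)
  a <- matrix(rnorm(150 * 3, 0, 0.1), 150, 3)
  b <- matrix(rnorm(150 * 3, 5, 0.1), 150, 3)
  x <- rbind(a, b)
  dimnames(x) <- list(sprintf("g%03d", 1:300), paste0("s", 1:3))
  m <- train_som(x, som_config(rows = 2, cols = 2, epochs = 10,
                               centering = FALSE, seed = 1,
                               radius_final = 0.5))
  ua <- unique(m$assignment[1:150])
  ub <- unique(m$assignment[151:300])
  expect_length(intersect(ua, ub), 0)
})

test_that("NaN or single-sample input is rejected", {
  x <- matrix(c(1, NaN, 2, 3), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(train_som(x, som_config(rows = 2, cols = 2)), "finite")
  x1 <- matrix(1:4, 4, 1, dimnames = list(letters[1:4], "s1"))
  expect_error(train_som(x1, som_config(rows = 2, cols = 2)), "two samples")
})

test_that("landscape units equal the brute-force group-by mean", {
  set.seed(42)
  x <- matrix(rnorm(120 * 3), 120, 3,
              dimnames = list(sprintf("g%03d", 1:120), paste0("s", 1:3)))
  assignment <- sample(1:12, 120, replace = TRUE)
  model <- toy_model(x, 3, 4, assignment)
  for (s in colnames(x)) {
    ls <- landscape(model, s)
    for (u in 1:12) {
      rc <- unit_coords(u, 4)
      idx <- which(assignment == u)
      expect_equal(ls$grid[rc], mean(x[idx, s]))
    }
    expect_equal(ls$max_exp, max(ls$grid[!ls$empty]))
    expect_equal(ls$min_exp, min(ls$grid[!ls$empty]))
  }
  expect_error(landscape(model, "nope"), "unknown sample")

  ## empty units carry the codebook value and are flagged
  assignment2 <- rep(1:2, 60)  # units 3..12 empty
  model2 <- toy_model(x, 3, 4, assignment2)
  ls2 <- landscape(model2, "s1")
  expect_true(all(ls2$empty[cbind(c(1, 3), c(3, 4))]))
  expect_equal(sum(!ls2$empty), 2)
})

test_that("constant input yields a flat landscape and no classification", {
  x <- matrix(5, 40, 3, dimnames = list(sprintf("g%02d", 1:40),
                                        paste0("s", 1:3)))
  model <- toy_model(x, 2, 2, rep(1:4, 10))
  ls <- landscape(model, "s1")
  expect_equal(ls$max_exp, ls$min_exp)
  cls <- classify_metagenes(ls)
  expect_true(all(cls == "none"))
})

test_that("lattice neighbours have closer codebooks than random pairs", {
  model <- demo_run(1)$model
  cb <- model$codebook
  co <- unit_coords(seq_len(nrow(cb)), model$config$cols)
  set.seed(43)
  pick <- sample(nrow(cb), 150, replace = TRUE)
  adj_d <- c(); rnd_d <- c()
  for (u in pick) {
    nb <- which(abs(co[, 1] - co[u, 1]) <= 1 & abs(co[, 2] - co[u, 2]) <= 1)
    nb <- setdiff(nb, u)
    v <- sample(nb, 1)
    adj_d <- c(adj_d, sqrt(sum((cb[u, ] - cb[v, ])^2)))
    w <- sample(setdiff(seq_len(nrow(cb)), u), 1)
    rnd_d <- c(rnd_d, sqrt(sum((cb[u, ] - cb[w, ])^2)))
  }
  expect_lt(mean(adj_d), mean(rnd_d))
})

test_that("spot connectivity semantics distinguish 4- and 8-adjacency", {
  cls <- matrix("none", 5, 5)
  cls[1, 1] <- "over"
  sp1 <- detect_spots(cls)
  expect_length(sp1, 1)
  expect_equal(unname(sp1[[1]]$units[1, ]), c(1, 1))

  cls[2, 2] <- "over"  # diagonal pair
  expect_length(detect_spots(cls, adjacency = 4), 2)
  expect_length(detect_spots(cls, adjacency = 8), 1)

  expect_length(detect_spots(matrix("none", 3, 3)), 0)
})

test_that("spots partition classified units and order by size", {
  set.seed(44)
  for (i in 1:20) {
    cls <- matrix(sample(c("over", "under", "none"), 100, TRUE,
                         prob = c(.2, .2, .6)), 10, 10)
    for (adj in c(4, 8)) {
      spots <- detect_spots(cls, adj)
      for (klass in c("over", "under")) {
        units <- do.call(rbind, lapply(
          Filter(function(s) s$class == klass, spots), `[[`, "units"))
        want <- which(cls == klass, arr.ind = TRUE)
        if (is.null(units)) {
          expect_equal(nrow(want), 0)
        } else {
          expect_equal(nrow(units), nrow(want))
          expect_setequal(paste(units[, 1], units[, 2]),
                          paste(want[, 1], want[, 2]))
        }
      }
      sizes <- vapply(spots, function(s) s$size, 0)
      expect_true(all(diff(sizes) <= 0))
    }
  }
})

test_that("spot summary bookkeeping is consistent", {
  run <- demo_run(1)
  summ <- spot_summary(run$spots)
  expect_equal(nrow(summ$table),
               sum(lengths(run$spots)))
  ## each incidence row sums to the gene's total spot memberships
  memb <- integer(nrow(summ$incidence))
  names(memb) <- rownames(summ$incidence)
  for (s in names(run$spots)) for (sp in run$spots[[s]])
    memb[sp$genes] <- memb[sp$genes] + 1L
  expect_equal(unname(rowSums(summ$incidence)), unname(memb))
  ## spots within one sample/class are disjoint in units and genes
  for (s in names(run$spots)) {
    for (klass in c("over", "under")) {
      sps <- Filter(function(x) x$class == klass, run$spots[[s]])
      gs <- unlist(lapply(sps, `[[`, "genes"))
      expect_false(anyDuplicated(gs) > 0)
    }
  }
  expect_equal(nrow(spot_summary(list(s1 = list()))$table), 0)
})

test_that("trained quantization error stays at the initial-codebook level", {
  ## data-row initialization is already a strong quantizer; training with
  ## a non-collapsing neighbourhood trades a few percent of quantization
  ## accuracy for topographic order, so qe may sit slightly above the
  ## initial value but must not drift away from it
  model <- demo_run(1)$model
  expect_lt(model$qe, model$qe_initial * 1.1)
  ## and qe matches an independent recomputation from the assignment data
  probe <- seq(1, nrow(model$data), by = 13)
  d <- vapply(probe, function(g)
    min(sqrt(rowSums(sweep(model$codebook, 2, model$data[g, ])^2))), 0)
  assigned_d <- vapply(probe, function(g) {
    u <- model$assignment[g]
    sqrt(sum((model$codebook[u, ] - model$data[g, ])^2))
  }, 0)
  expect_equal(assigned_d, d, tolerance = 1e-9)
})
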