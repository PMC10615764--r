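# FC construction, vectorization, graph binarization and normalization.

test_that("pearson_fc matches hand values and the brute-force formula", {
  x <- c(1, 2, 3, 4)
  ts <- cbind(a = x, b = 2 * x, c = rev(x), d = c(1, 3, 2, 4))
  fc <- pearson_fc(ts)
  expect_equal(fc["a", "b"], 1)
  expect_equal(fc["a", "c"], -1)
  expect_equal(fc["a", "d"], 0.8)

  set.seed(1)
  for (rep in 1:100) {
    ts <- matrix(rnorm(sample(5:20, 1) * 6), ncol = 6)
    expect_lt(max(abs(pearson_fc(ts) - oracle_pearson(ts))), 1e-12)
  }

  expect_error(pearson_fc(matrix(1:4, 2, 2)), "3 timepoints")
  tsc <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(pearson_fc(tsc), "b")
})

test_that("vectorize_upper uses lexicographic order and round-trips", {
  fc <- diag(3)
  fc[1, 2] <- fc[2, 1] <- 0.1
  fc[1, 3] <- fc[3, 1] <- 0.2
  fc[2, 3] <- fc[3, 2] <- 0.3
  expect_equal(vectorize_upper(fc), c(0.1, 0.2, 0.3))
  expect_equal(length(vectorize_upper(diag(112))), 6216)
  set.seed(2)
  m <- devectorize_upper(rnorm(45))
  expect_equal(devectorize_upper(vectorize_upper(m)), m)
})

test_that("binarize_topk keeps exactly ceil(sparsity * P) with lexicographic ties", {
  fc <- devectorize_upper(c(0.9, -0.5, 0.1))
  adj <- binarize_topk(fc, 0.5)   # K = 2: |0.9| and |-0.5|
  expect_equal(sum(adj[upper.tri(adj)]), 2)
  expect_equal(adj[1, 2], 1)
  expect_equal(adj[1, 3], 1)
  expect_equal(adj[2, 3], 0)

  # all ties: lexicographically first pairs win
  fc4 <- devectorize_upper(rep(0.4, 6))
  adj4 <- binarize_topk(fc4, 0.5)  # K = 3 -> (1,2), (1,3), (1,4)
  expect_equal(adj4[cbind(1, 2:4)], c(1, 1, 1))
  expect_equal(adj4[cbind(c(2, 2, 3), c(3, 4, 4))], c(0, 0, 0))

  # boundary: near-1 sparsity keeps everything
  expect_equal(sum(binarize_topk(fc, 0.999)[upper.tri(fc)]), 3)

  # exact count on random and tie-heavy integer matrices
  set.seed(3)
  for (rep in 1:200) {
    r <- sample(5:15, 1)
    v <- if (rep %% 2) rnorm(r * (r - 1) / 2) else
      sample(-2:2, r * (r - 1) / 2, replace = TRUE) / 2
    sp <- runif(1, 0.05, 0.95)
    adj <- binarize_topk(devectorize_upper(v), sp)
    expect_identical(sum(adj[upper.tri(adj)]),
                     ceiling(sp * length(v)))
    expect_identical(adj, t(adj))
    expect_true(all(diag(adj) == 0))
  }
})

test_that("build_graph keeps pre-binarization profiles as node features", {
  set.seed(4)
  fc <- devectorize_upper(runif(45, -0.8, 0.8))
  g <- build_graph(fc, 0.5)
  expect_equal(g$node_features[upper.tri(fc)], fc[upper.tri(fc)])
  expect_true(all(diag(g$node_features) == 0))

  # a dominant edge survives any sparsity level
  v <- runif(45, -0.3, 0.3); v[1] <- 0.95
  for (sp in c(0.05, 0.3, 0.7)) {
    expect_equal(build_graph(devectorize_upper(v), sp)$adjacency[1, 2], 1)
  }
})

test_that("graph construction is invariant to common rescaling of series", {
  set.seed(5)
  ts <- matrix(rnorm(200), 20, 10)
  g1 <- build_graph(pearson_fc(ts))
  g2 <- build_graph(pearson_fc(ts * 37.5))
  expect_equal(g1$adjacency, g2$adjacency)
  expect_equal(g1$node_features, g2$node_features)
})

test_that("normalize_adjacency is the symmetric renormalized operator", {
  # two nodes, one edge: D = diag(2, 2), all entries 1/2
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(a), matrix(0.5, 2, 2))

  # isolated node keeps a unit self-loop
  a3 <- matrix(0, 3, 3); a3[1, 2] <- a3[2, 1] <- 1
  ah <- normalize_adjacency(a3)
  expect_equal(ah[3, 3], 1)

  set.seed(6)
  adj <- binarize_topk(devectorize_upper(rnorm(45)), 0.4)
  ah <- normalize_adjacency(adj)
  expect_lt(max(abs(ah - t(ah))), 1e-12)
  expect_true(all(ah >= 0))
})
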