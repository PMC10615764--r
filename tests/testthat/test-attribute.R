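# Attribution: edge-mask explainer, region ablation, consensus ranking.

# Hand-built 1-layer GCN whose output depends only on propagation entry
# (a, b): the single feature column the conv weight reads is e_a, so the
# hidden activation of node i is S[i, a] — nonzero only through a's
# self-loop and the (a, b) edge.
oracle_edge_model <- function(r = 8, a = 3, b = 7, bias = -0.5) {
  adj <- matrix(0, r, r)
  adj[a, b] <- adj[b, a] <- 1
  adj[1, 2] <- adj[2, 1] <- 1   # decoy edge, not incident to a or b
  x <- matrix(0, r, r)
  x[a, b] <- x[b, a] <- 1       # feature column b = e_a
  w1 <- matrix(0, r, 1); w1[b, 1] <- 1
  model <- new_gcn_model(w = list(w1), w_out = matrix(10, 1, 1), b = bias)
  graph <- structure(list(adjacency = adj, node_features = x,
                          region_labels = sprintf("R%d", seq_len(r))),
                     class = "connectome_graph")
  list(model = model, graph = graph)
}

test_that("the mask explainer finds the only informative edge", {
  o <- oracle_edge_model()
  labels <- factor("pos", levels = c("neg", "pos"))
  ex <- explain_gcn(o$model, list(o$graph), labels, epochs = 150, seed = 2)
  expect_equal(c(ex$top_edges$i[1], ex$top_edges$j[1]), c(3, 7))
  expect_gt(ex$top_edges$weight[1], 2 * ex$top_edges$weight[2])
  # the mask is symmetric, zero-diagonal, in [0, 1]
  expect_equal(ex$mask, t(ex$mask))
  expect_true(all(diag(ex$mask) == 0))
  expect_true(all(ex$mask >= 0 & ex$mask <= 1))
  # objective decreases over optimization
  expect_lt(ex$objective_trace[length(ex$objective_trace)],
            ex$objective_trace[1])
})

test_that("a large size penalty drives the mask toward zero", {
  o <- oracle_edge_model()
  labels <- factor("pos", levels = c("neg", "pos"))
  ex <- explain_gcn(o$model, list(o$graph), labels, epochs = 400,
                    lambda_size = 100, seed = 2)
  expect_lt(max(ex$mask), 0.2)
})

test_that("two equally informative edges share the top ranks", {
  r <- 8; a <- 3; b <- 7; cc <- 2; d <- 5
  adj <- matrix(0, r, r)
  adj[a, b] <- adj[b, a] <- 1
  adj[cc, d] <- adj[d, cc] <- 1
  x <- matrix(0, r, r)
  x[a, b] <- x[b, a] <- 1
  x[cc, d] <- x[d, cc] <- 1
  w1 <- matrix(0, r, 2); w1[b, 1] <- 1; w1[d, 2] <- 1
  model <- new_gcn_model(w = list(w1), w_out = matrix(c(5, 5), 2, 1), b = -0.5)
  graph <- structure(list(adjacency = adj, node_features = x,
                          region_labels = sprintf("R%d", seq_len(r))),
                     class = "connectome_graph")
  labels <- factor("pos", levels = c("neg", "pos"))
  for (s in 1:5) {
    ex <- explain_gcn(model, list(graph), labels, epochs = 120, seed = s)
    top2 <- paste(ex$top_edges$i[1:2], ex$top_edges$j[1:2])
    expect_setequal(top2, c("3 7", "2 5"))
  }
})

test_that("explainer errors when nothing is classified correctly", {
  o <- oracle_edge_model()
  wrong <- factor("neg", levels = c("neg", "pos"))  # model predicts pos
  expect_error(explain_gcn(o$model, list(o$graph), wrong), "correctly")
})

test_that("ablation attributes the drop to the planted hub region", {
  co <- cached("abl_cohort", generate_cohort(null_config(
    n_regions = 15, n_per_group = 80, n_sites = 2,
    hub_effect = list(region = 5, d = 0.9), seed = 31)))
  # small-cohort training budget: fewer subjects need a larger learning
  # rate and smaller batches to reach a comparable number of Adam steps
  spec <- model_spec("gcn", grid = data.frame(hidden = 8, n_layers = 2),
                     epochs = 60, lr = 0.01, decay_every = 30,
                     dropout = 0.3, batch_size = 16)
  ab <- ablate_region(co, "mdd_vs_hc", spec, n_repeats = 2, seed = 17)
  expect_equal(nrow(ab$regions), 15)
  expect_true(all(ab$regions$sd_drop >= 0))
  expect_equal(which.max(ab$regions$mean_drop), 5)
  # an untouched region never beats the planted hub
  expect_gt(ab$regions$mean_drop[5], max(ab$regions$mean_drop[-5]))
})

test_that("masking every region removes all class information", {
  co <- cached("abl_cohort", generate_cohort(null_config(
    n_regions = 15, n_per_group = 80, n_sites = 2,
    hub_effect = list(region = 5, d = 0.9), seed = 31)))
  y <- factor(co$manifest$diagnosis, levels = c("HC", "MDD"))
  g <- cohort_graphs(co)
  set.seed(8)
  idx <- sample(160); tr <- idx[1:120]; te <- idx[121:160]
  m <- gcn_train(g[tr], y[tr], hidden = 8, epochs = 60, lr = 0.01,
                 decay_every = 30, dropout = 0.3, batch_size = 16, seed = 2)
  masked <- lapply(co$fc[te], function(fc) {
    build_graph(mask_region_fc(fc, 1:15), labels = co$region_labels)
  })
  pred <- factor(m$levels[(gcn_predict(m, masked) >= 0.5) + 1], levels = m$levels)
  acc <- evaluate_metrics(y[te], pred, "MDD")$balanced_accuracy
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
})

fake_ablation <- function(labels, drops) {
  structure(list(regions = tibble::tibble(
    region = seq_along(labels), label = labels,
    mean_drop = drops, sd_drop = 0),
    region_labels = labels), class = "ablation_result")
}

test_that("rank consensus intersects top-k sets by mean rank", {
  labs <- sprintf("R%d", 1:12)
  a <- fake_ablation(labs, drops = 12:1)
  b <- fake_ablation(labs, drops = 12:1)
  same <- rank_consensus(a, b, top_k = 5)
  expect_equal(same$id, labs[1:5])

  c2 <- fake_ablation(labs, drops = 1:12)
  expect_equal(nrow(rank_consensus(a, c2, top_k = 5)), 0)

  # x first in A, third in B -> mean rank 2
  d_a <- c(10, 1, 1, 1, 9, 8, 7, 0, 0, 0, 0, 0)    # x = R1 rank 1
  d_b <- c(8, 0, 0, 0, 10, 9, 7, 0, 0, 0, 0, 0)    # x = R1 rank 3
  mix <- rank_consensus(fake_ablation(labs, d_a), fake_ablation(labs, d_b),
                        top_k = 4)
  expect_equal(mix$mean_rank[mix$id == "R1"], 2)

  bad <- fake_ablation(paste0("X", labs), drops = 12:1)
  expect_error(rank_consensus(a, bad), "labels differ")
})
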