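test_that("graph_conv_layer matches a dense linear-algebra oracle", {
  # single isolated node: self-loop only, degree 1 -> tanh(x %*% w)
  lone <- as_binary_adjacency(matrix(0L, 1, 1))
  x <- matrix(c(0.3, -0.2), 1)
  w <- matrix(c(0.5, -1, 2, 0.1, 0, 1), 2)
  expect_equal(graph_conv_layer(lone, x, w), tanh(x %*% w))

  # zero weights give zero output on any graph
  set.seed(5)
  a <- as_binary_adjacency(random_adjacency(6, 0.4))
  xf <- matrix(rnorm(6 * 3), 6)
  expect_equal(graph_conv_layer(a, xf, matrix(0, 3, 2)), matrix(0, 6, 2))

  # 3-node path with hand-set values against explicit D^-1 (A+I) X W
  path <- matrix(0L, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1L
  xp <- matrix(c(1, 0, -1, 2, 1, 0), 3)
  wp <- matrix(c(0.5, -0.25, 1, 0.75), 2)
  at <- path + diag(3)
  oracle <- tanh(diag(1 / rowSums(at)) %*% at %*% xp %*% wp)
  got <- graph_conv_layer(as_binary_adjacency(path), xp, wp)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(abs(got) < 1))
  expect_error(graph_conv_layer(as_binary_adjacency(path), xp[1:2, ], wp),
               "node count")
})

test_that("sort_pooling sorts, truncates, pads and breaks ties like the oracle", {
  x <- rbind(c(1, 0.5), c(2, 0.9))
  out <- sort_pooling(x, 3)
  expect_equal(out, rbind(c(2, 0.9), c(1, 0.5), c(0, 0)))
  expect_equal(sort_pooling(x, 1), rbind(c(2, 0.9)))

  set.seed(33)
  for (rep in 1:25) {
    # duplicate-heavy values force the tie-break path
    m <- matrix(sample(c(0, 0.25, 0.5, 1), 24, replace = TRUE), 6, 4)
    expect_equal(sort_pooling(m, 6), m[oracle_sortpool_order(m), , drop = FALSE])
  }
})

test_that("bce_loss matches analytic values and clips extremes", {
  expect_equal(bce_loss(rep(0.5, 7), rep(c(0, 1), length.out = 7)), log(2),
               tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), (-log(0.9) - log(0.8)) / 2,
               tolerance = 1e-12)
  expect_equal(round(bce_loss(c(0.9, 0.2), c(1, 0)), 5), 0.16425)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-6)  # epsilon floor, not -Inf
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
  expect_error(bce_loss(0.5, c(0, 1)), "length")
})

test_that("forward produces normalized, deterministic, permutation-invariant output", {
  graphs <- tiny_graphs()
  cfg <- tiny_config()
  params <- generic_params(cfg, 12)
  set.seed(91)
  for (g in graphs[1:4]) {
    p <- dgcnn_forward(g, params, cfg)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(p, dgcnn_forward(g, params, cfg))  # eval determinism
    perm <- sample(12)
    expect_equal(dgcnn_forward(permute_graph(g, perm), params, cfg), p,
                 tolerance = 1e-6)
  }
  bad <- generic_params(tiny_config(), 12)
  bad$W1 <- bad$W1[, 1:2]
  expect_error(dgcnn_forward(graphs[[1]], bad, cfg), "inconsistent")
})

test_that("train-mode dropout matches eval expectation under averaging", {
  graphs <- tiny_graphs()
  cfg <- tiny_config(dropout = 0.5)
  params <- generic_params(cfg, 12)
  g <- graphs[[1]]
  p_eval <- dgcnn_forward(g, params, cfg)
  set.seed(2024)
  acc <- c(0, 0)
  n_pass <- 2000
  for (i in seq_len(n_pass)) {
    acc <- acc + dgcnn_forward(g, params, cfg, mode = "train")
  }
  expect_equal(as.numeric(acc / n_pass), as.numeric(p_eval), tolerance = 0.05)
})

test_that("analytic gradients match central finite differences", {
  graphs <- tiny_graphs()
  cfg <- tiny_config()
  params <- generic_params(cfg, 12)
  gr <- dgcnn_gradients(graphs[1:4], params, cfg)
  expect_gte(gr$loss, 0)
  h <- 1e-6
  set.seed(55)
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(5, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (dgcnn_gradients(graphs[1:4], pp, cfg)$loss -
                dgcnn_gradients(graphs[1:4], pm, cfg)$loss) / (2 * h)
      ana <- gr$grads[[nm]][i]
      denom <- max(abs(ana) + abs(num), 1e-6)
      expect_lt(abs(ana - num) / denom, 1e-4)
    }
  }
})

test_that("training is reproducible, rejects single-class input, and learns", {
  graphs <- tiny_graphs(n_subj = 12)
  cfg <- tiny_config(epochs = 10, dropout = 0.5)
  m1 <- train_dgcnn(graphs, config = cfg)
  m2 <- train_dgcnn(graphs, config = cfg)
  expect_identical(m1$history, m2$history)        # bit-identical
  expect_identical(m1$params, m2$params)
  expect_true(all(m1$history$train_loss >= 0))
  expect_equal(nrow(m1$history), 10)

  only_mdd <- Filter(function(g) g$label == "MDD", graphs)
  expect_error(train_dgcnn(only_mdd, config = cfg), "both classes")

  # separable cohort: loss trends down over the first 10 epochs
  spec <- synthetic_cohort_spec(n_per_group = 30, n_rois = 12, T_len = 150,
                                n_blocks = 3, effect_delta = 0.4, seed = 9)
  sep <- cohort_to_graphs(generate_cohort(spec), 0.3)
  cfg2 <- dgcnn_config(conv_channels = c(8, 8, 8, 1), filters1 = 8,
                       filters2 = 8, width2 = 3, dense_width = 16,
                       dropout = 0.5, epochs = 10, batch_size = 20,
                       learning_rate = 0.005, seed = 4, k = 12)
  m <- train_dgcnn(sep, config = cfg2)
  loss <- m$history$train_loss
  expect_lt(loss[10], loss[1])
  expect_lte(sum(diff(loss) > 0), 2)              # allow single-epoch noise
})

test_that("predict matches per-graph forward output and preserves order", {
  graphs <- tiny_graphs()
  cfg <- tiny_config(epochs = 2)
  m <- train_dgcnn(graphs, config = cfg)
  preds <- predict(m, graphs)
  expect_equal(nrow(preds), length(graphs))
  for (i in seq_along(graphs)) {
    p <- dgcnn_forward(graphs[[i]], m$params, m$config)
    expect_equal(c(preds$p_NC[i], preds$p_MDD[i]), as.numeric(p),
                 tolerance = 1e-12)
    expect_identical(preds$subject_id[i], graphs[[i]]$subject_id)
  }
  expect_identical(preds, predict(m, graphs))     # deterministic
  empty <- predict(m, list())
  expect_equal(nrow(empty), 0)
})
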