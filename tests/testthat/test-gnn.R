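# Recurrent GNN: initialization, message passing, loss, gradients, training.

# Minimal hand-made graph: a path 1-2-3 with 2-dim node and 1-dim edge
# features.
toy_path_graph <- function(n = 3L, X = NULL) {
  if (is.null(X)) X <- matrix(seq_len(2 * n) / 10, n, 2)
  colnames(X) <- c("f1", "f2")
  structure(list(
    protein_id = "toy",
    nodes = data.frame(chain = "A", resno = seq_len(n), ins = "",
                       aa = "GLY", key = paste0("A:", seq_len(n)),
                       stringsAsFactors = FALSE),
    X = X,
    edges = data.frame(i = seq_len(n - 1L), j = seq.int(2L, n)),
    E = matrix(1, n - 1L, 1L, dimnames = list(NULL, "e")),
    node_schema = ppiface:::new_feature_schema(list(f = c("f1", "f2"))),
    edge_schema = ppiface:::new_feature_schema(list(e = "e"))),
    class = "protein_graph")
}

test_that("initialization is seed-deterministic with the right shapes", {
  cfg <- gnn_config(state_dim = 4L, net_s_hidden = 16L, net_o_hidden = 8L,
                    seed = 5L)
  m1 <- init_model(cfg, 10L, 3L)
  m2 <- init_model(cfg, 10L, 3L)
  expect_identical(m1$params, m2$params)
  expect_equal(dim(m1$params$W1s), c(23L, 16L))
  expect_equal(dim(m1$params$W1x), c(4L, 16L))
  expect_equal(dim(m1$params$W2), c(16L, 4L))
  expect_equal(dim(m1$params$V1), c(14L, 8L))
  expect_equal(dim(m1$params$V2), c(8L, 1L))
  # no hidden layers -> single affine maps
  m0 <- init_model(gnn_config(state_dim = 4L, net_s_hidden = 0L,
                              net_o_hidden = 0L), 10L, 3L)
  expect_null(m0$params$W2)
  expect_null(m0$params$V2)
  expect_equal(dim(m0$params$W1s), c(23L, 4L))
  expect_equal(dim(m0$params$V1), c(14L, 1L))  # state_dim + node_dim
})

test_that("state update matches a hand-unrolled linear computation", {
  g <- toy_path_graph()
  cfg <- gnn_config(state_dim = 2L, max_iter = 1L, net_s_hidden = 0L,
                    net_o_hidden = 0L)
  m <- init_model(cfg, 2L, 1L)
  # hand-chosen linear state map
  m$params$W1s <- matrix(c(0.1, -0.2, 0.3, 0.05, -0.1,
                           0.02, 0.04, -0.06, 0.08, 0.1) / 2, 5, 2)
  m$params$W1x <- matrix(c(0.5, 0.1, -0.3, 0.2), 2, 2)
  m$params$b1 <- c(0.01, -0.02)
  states <- matrix(c(1, 0, -1, 0.5, 0.2, -0.4), 3, 2)
  got <- state_update(g, states, m)
  # manual unrolling: x_n <- sum_m f(l_n, l_m, e_nm, x_m)
  nbrs <- list(`1` = 2L, `2` = c(1L, 3L), `3` = 2L)
  want <- matrix(0, 3, 2)
  for (n in 1:3) for (mm in nbrs[[as.character(n)]]) {
    u <- c(g$X[n, ], g$X[mm, ], 1)
    want[n, ] <- want[n, ] + drop(u %*% m$params$W1s) +
      drop(states[mm, ] %*% m$params$W1x) + m$params$b1
  }
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("isolated nodes receive the zero aggregate", {
  g <- toy_path_graph(4L)
  g$edges <- data.frame(i = 1L, j = 2L)   # nodes 3 and 4 isolated
  g$E <- g$E[1, , drop = FALSE]
  m <- init_model(gnn_config(state_dim = 3L, net_s_hidden = 0L), 2L, 1L)
  got <- state_update(g, matrix(0.5, 4, 3), m)
  expect_equal(got[3, ], rep(0, 3))
  expect_equal(got[4, ], rep(0, 3))
  expect_false(all(got[1, ] == 0))
})

test_that("zeroed output weights give probability one half everywhere", {
  tc <- tiny_complex()
  m <- init_model(gnn_config(state_dim = 4L, net_o_hidden = 0L), 89L, 11L)
  m$params$V1[] <- 0
  m$params$c1[] <- 0
  expect_equal(gnn_forward(tc$graph, m), rep(0.5, nrow(tc$graph$nodes)))
})

test_that("forward is permutation-equivariant", {
  tc <- tiny_complex()
  cfg <- gnn_config(state_dim = 6L, max_iter = 3L, net_s_hidden = 8L,
                    net_o_hidden = 4L, seed = 2L)
  m <- init_model(cfg, 89L, 11L)
  p0 <- gnn_forward(tc$graph, m)
  set.seed(1)
  perm <- sample.int(nrow(tc$graph$nodes))
  g2 <- tc$graph
  g2$nodes <- g2$nodes[perm, ]
  g2$X <- g2$X[perm, ]
  inv <- match(seq_along(perm), perm)
  g2$edges <- data.frame(i = pmin(inv[tc$graph$edges$i], inv[tc$graph$edges$j]),
                         j = pmax(inv[tc$graph$edges$i], inv[tc$graph$edges$j]))
  p1 <- gnn_forward(g2, m)
  expect_lt(max(abs(p1 - p0[perm])), 1e-10)
})

test_that("nodes beyond graph distance max_iter cannot influence an output", {
  n <- 9L
  g <- toy_path_graph(n)
  cfg <- gnn_config(state_dim = 5L, max_iter = 3L, net_s_hidden = 6L,
                    net_o_hidden = 4L, seed = 3L)
  m <- init_model(cfg, 2L, 1L)
  p0 <- gnn_forward(g, m)
  g2 <- g
  g2$X[n, ] <- g2$X[n, ] + 100   # node at distance 8 from node 1
  p1 <- gnn_forward(g2, m)
  expect_equal(p1[1], p0[1])
  expect_equal(p1[2], p0[2])     # distance 7
  expect_false(isTRUE(all.equal(p1[n - 1L], p0[n - 1L])))  # distance 1
})

test_that("backprop gradients match central finite differences", {
  cx <- generate_complex(synthetic_spec(seed = 12,
                                        residues_per_chain = c(10, 10)))
  g <- build_graph(cx$residue_set,
                   assign_secondary_structure(cx$residue_set),
                   detect_bonds(cx$residue_set))
  y <- cx$labels$labels
  set.seed(9)
  for (arch in list(c(0L, 0L), c(6L, 4L))) {
    cfg <- gnn_config(state_dim = 4L, max_iter = 3L,
                      net_s_hidden = arch[1], net_o_hidden = arch[2],
                      seed = 4L)
    m <- init_model(cfg, ncol(g$X), ncol(g$E))
    m$node_center <- colMeans(g$X)
    sdv <- apply(g$X, 2, sd); sdv[sdv < 1e-8] <- 1
    m$node_scale <- sdv
    fw <- ppiface:::.forward_internal(m, g, keep = TRUE)
    gr <- ppiface:::.backward(m, fw, y, w_pos = 3)
    lossfun <- function(mm)
      as.numeric(gnn_loss(gnn_forward(g, mm), y, w_pos = 3))
    for (k in names(m$params)) {
      idx <- sample(seq_along(m$params[[k]]),
                    min(4L, length(m$params[[k]])))
      for (i in idx) {
        eps <- 1e-5
        mp <- m; mp$params[[k]][i] <- mp$params[[k]][i] + eps
        mn <- m; mn$params[[k]][i] <- mn$params[[k]][i] - eps
        fd <- (lossfun(mp) - lossfun(mn)) / (2 * eps)
        rel <- abs(fd - gr[[k]][i]) /
          max(1e-8, abs(fd) + abs(gr[[k]][i]))
        expect_lt(rel, 1e-4)
      }
    }
  }
})

test_that("loss weighting hits both printed endpoints and the midpoint", {
  labels <- c(rep(1, 20), rep(0, 80))    # ratio N_neg / N_pos = 4
  expect_equal(positive_weight(labels, 0), 1)
  expect_equal(positive_weight(labels, 1), 4)
  expect_equal(positive_weight(labels, 0.5), 2.5)
  # with wbal = 1 total positive weight equals total negative weight
  w_pos <- positive_weight(labels, 1)
  expect_equal(sum(ifelse(labels == 1, w_pos, 0)),
               sum(ifelse(labels == 0, 1, 0)))
  expect_error(positive_weight(rep(0, 10), 0.5), "no positive")
  # monotone and continuous in w_pos for fixed predictions
  set.seed(2)
  probs <- runif(100)
  losses <- vapply(seq(1, 4, by = 0.5), function(w)
    as.numeric(gnn_loss(probs, labels, w_pos = w)), numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("training reduces the loss on an easy planted problem", {
  corpus <- generate_corpus(6, synthetic_spec(seed = 19,
                                              residues_per_chain = c(20, 20),
                                              feature_signal = 1,
                                              noise_sd = 0.1))
  samples <- corpus_samples(corpus, "whole")
  fit <- gnn_train(samples[1:4], samples[5:6],
                   fast_config(epochs = 10L, learning_rate = 0.02))
  h <- fit$history$epochs
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_gt(fit$history$best_fscore, 0.5)
})

test_that("training is seed-reproducible", {
  corpus <- generate_corpus(4, synthetic_spec(seed = 23,
                                              residues_per_chain = c(15, 15)))
  samples <- corpus_samples(corpus, "whole")
  f1 <- gnn_train(samples[1:3], samples[4], fast_config(epochs = 3L))
  f2 <- gnn_train(samples[1:3], samples[4], fast_config(epochs = 3L))
  expect_identical(f1$history$epochs, f2$history$epochs)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("flat validation triggers early stopping", {
  corpus <- generate_corpus(4, synthetic_spec(seed = 29,
                                              residues_per_chain = c(15, 15)))
  samples <- corpus_samples(corpus, "whole")
  val <- samples[4]
  val[[1]]$labels[] <- 0L   # degenerate validation: F-score stuck at 0
  fit <- gnn_train(samples[1:3], val,
                   fast_config(epochs = 30L, early_stopping_patience = 3L,
                               wbal = 1))
  expect_true(fit$history$stopped_early)
  expect_lte(nrow(fit$history$epochs), 10L)
})

test_that("grid search returns the singleton and prefers true labels", {
  corpus <- generate_corpus(6, synthetic_spec(seed = 37,
                                              residues_per_chain = c(20, 20),
                                              feature_signal = 1,
                                              noise_sd = 0.1))
  samples <- corpus_samples(corpus, "whole")
  tr <- samples[1:4]; va <- samples[5:6]
  gs <- grid_search(list(state_dim = 8L), tr, va,
                    base_config = fast_config(epochs = 4L))
  expect_equal(gs$best_config$state_dim, 8L)
  expect_equal(nrow(gs$results), 1L)
  # planted comparison: shuffling training labels destroys the signal
  tr_shuf <- lapply(tr, function(s) {
    s$labels <- ppiface:::with_local_seed(99, sample(s$labels))
    s
  })
  f_true <- gnn_train(tr, va, fast_config(epochs = 6L))
  f_shuf <- gnn_train(tr_shuf, va, fast_config(epochs = 6L))
  ev_true <- evaluate_model(f_true$model, va)
  ev_shuf <- evaluate_model(f_shuf$model, va)
  expect_gt(ev_true$fscore, ev_shuf$fscore)
})

test_that("prediction calls follow the threshold convention and are monotone", {
  tc <- tiny_complex()
  m <- init_model(gnn_config(state_dim = 4L, seed = 8L), 89L, 11L)
  pred <- gnn_predict(m, tc$graph, threshold = 0.5)
  expect_equal(pred$call, as.integer(pred$probability >= 0.5))
  # boundary: probability exactly at threshold is called positive
  m0 <- m; m0$params$V1[] <- 0; m0$params$c1[] <- 0
  if (!is.null(m0$params$V2)) { m0$params$V2[] <- 0; m0$params$c2[] <- 0 }
  pred0 <- gnn_predict(m0, tc$graph, threshold = 0.5)
  expect_true(all(pred0$probability == 0.5))
  expect_true(all(pred0$call == 1L))
  # monotone under a threshold sweep
  prev <- rep(1L, nrow(pred))
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    cur <- gnn_predict(m, tc$graph, threshold = th)$call
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("model checkpoints round-trip exactly", {
  tc <- tiny_complex()
  cfg <- gnn_config(state_dim = 4L, net_s_hidden = 6L, net_o_hidden = 3L,
                    seed = 31L)
  m <- init_model(cfg, 89L, 11L)
  m$node_center <- colMeans(tc$graph$X)
  dir <- tempfile()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(gnn_forward(tc$graph, m2), gnn_forward(tc$graph, m))
  expect_equal(m2$config$state_dim, 4L)
})
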