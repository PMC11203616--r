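test_that("initial states are seeded, scaled and zero-centred", {
  cfg <- propagation_config(K = 6L, state_dim = 10L, init_scale = 0.1,
                            seed = 21L)
  x1 <- init_states(100L, cfg)
  expect_identical(x1, init_states(100L, cfg))
  expect_identical(attr(x1, "iteration"), 0L)
  expect_true(all(abs(x1) <= 0.1))
  # degenerate limit: scale 0 gives all-zero states
  cfg0 <- propagation_config(K = 6L, state_dim = 3L, init_scale = 0)
  expect_equal(unclass(init_states(5L, cfg0)),
               matrix(0, 5L, 3L), ignore_attr = TRUE)
  # CLT bound: per-dimension mean of a 10000 x 10 draw within 4 standard
  # errors of 0 (uniform(-s, s) has sd s/sqrt(3))
  big <- init_states(10000L, propagation_config(K = 1L, state_dim = 10L,
                                                init_scale = 0.1,
                                                seed = 77L))
  se <- (0.1 / sqrt(3)) / sqrt(10000L)
  expect_true(all(abs(colMeans(big)) < 4 * se))
})

test_that("an isolated node receives the zero message", {
  g <- molecular_graph("C", targets = 1)
  m <- gnn_model(state_dim = 2L, n_tasks = 1L, hidden_state = 3L,
                 activation = "tanh", K = 1L, seed = 4L)
  b <- batch_graphs(list(g))
  st <- init_states(1L, m$prop)
  stepped <- gnn_step(b, st, m)
  # manual: f_w applied to (x, zero message of dim d_x + d_l + d_e)
  u <- cbind(st, matrix(0, 1L, 2L))
  expect_equal(unclass(stepped), unclass(mlp_forward(m$params$f, m$f_spec, u)),
               ignore_attr = TRUE)
  expect_identical(attr(stepped, "iteration"), 1L)
})

test_that("a 2-node single-edge step matches scalar arithmetic", {
  g <- molecular_graph(c("C", "C"), rbind(c(1L, 2L)), targets = 1)
  m <- gnn_model(state_dim = 1L, n_tasks = 1L, hidden_state = 1L,
                 activation = "tanh", K = 1L, init_scale = 0.1, seed = 12L)
  # hand-set weights: f input is (x_n, x_m); one hidden unit
  m$params$f <- list(W1 = matrix(c(0.5, -0.25), 2L, 1L), b1 = 0.1,
                     W2 = matrix(2), b2 = -0.3)
  b <- batch_graphs(list(g))
  x0 <- init_states(2L, m$prop)
  x1 <- gnn_step(b, x0, m)
  by_hand <- function(xs, xn) tanh(2 * tanh(0.5 * xs - 0.25 * xn + 0.1) - 0.3)
  expect_equal(as.numeric(x1), c(by_hand(x0[1L], x0[2L]),
                                 by_hand(x0[2L], x0[1L])),
               tolerance = 1e-12)
})

test_that("propagate composes steps and respects K", {
  gs <- lapply(1:3, function(s) heterogenize(rand_fixture_graph(4L, s)))
  b <- batch_graphs(gs)
  m <- cgnn_model(state_dim = 2L, n_tasks = 1L, hidden_state = 3L,
                  activation = "selu", K = 6L, init_scale = 0.05, seed = 2L)
  # K = 0: propagate returns the seeded init states untouched
  m0 <- m; m0$prop$K <- 0L
  expect_equal(propagate(b, m0), init_states(sum(b$n_nodes), m$prop))
  # K = 1 equals one manual step; K = 6 equals six chained steps
  st <- init_states(sum(b$n_nodes), m$prop)
  m1 <- m; m1$prop$K <- 1L
  expect_equal(unclass(propagate(b, m1)),
               unclass(cgnn_step(b, st, m)), ignore_attr = TRUE)
  for (t in 1:6) st <- cgnn_step(b, st, m)
  expect_equal(unclass(propagate(b, m)), unclass(st), ignore_attr = TRUE)
  expect_identical(attr(propagate(b, m), "iteration"), 6L)
  expect_error(propagation_config(K = -1L, state_dim = 2L), "non-negative")
})

test_that("propagation matches the naive per-node loop oracle", {
  # all graph sizes <= 4 nodes, d_x <= 2, random small weights, both kinds
  for (seed in 1:6) {
    n <- 1L + (seed %% 4L)
    d_x <- 1L + (seed %% 2L)
    g_raw <- rand_fixture_graph(n, seed = 100L + seed)
    for (kind in c("gnn", "cgnn")) {
      gs <- if (kind == "gnn") list(homogenize(g_raw))
        else list(heterogenize(g_raw))
      b <- batch_graphs(gs)
      m <- if (kind == "gnn") {
        gnn_model(d_x, 1L, node_feature_dim = 8L, hidden_state = 3L,
                  hidden_output = 3L, activation = "tanh", K = 3L,
                  init_scale = 0.1, seed = seed)
      } else {
        cgnn_model(d_x, 1L, hidden_state = 3L, hidden_output = 3L,
                   activation = "tanh", K = 3L, init_scale = 0.1,
                   seed = seed)
      }
      x0 <- init_states(sum(b$n_nodes), m$prop)
      ref_final <- ref_propagate(m, gs, x0)
      expect_equal(unclass(propagate(b, m)), unclass(ref_final),
                   tolerance = 1e-6, ignore_attr = TRUE)
      y <- graph_output(b, propagate(b, m), m)
      expect_equal(as.numeric(y), as.numeric(ref_graph_output(m, gs, ref_final)),
                   tolerance = 1e-6)
    }
  }
})

test_that("graph output is the mean of per-node outputs", {
  g <- heterogenize(molecular_graph(c("C", "O"), rbind(c(1L, 2L)),
                                    targets = 1))
  m <- cgnn_model(2L, 1L, hidden_state = 3L, K = 1L, seed = 6L)
  b <- batch_graphs(list(g))
  st <- propagate(b, m)
  per_node <- mlp_forward(m$params$out, m$out_spec,
                          cbind(st, b$node_features))
  expect_equal(as.numeric(graph_output(b, st, m)), mean(per_node))
  # outputs live strictly inside (0, 1)
  expect_true(all(graph_output(b, st, m) > 0 & graph_output(b, st, m) < 1))
})

test_that("a one-type composite model reproduces the standard GNN exactly", {
  # all-carbon graphs; message composition aligned by dropping the
  # neighbour-feature block from the GNN message
  gs_raw <- lapply(1:3, function(s)
    rand_fixture_graph(3L + s %% 2L, seed = 200L + s, elements = "C"))
  gnn <- gnn_model(3L, 1L, node_feature_dim = 0L, hidden_state = 4L,
                   activation = "relu", K = 6L, include_neighbor_label = FALSE,
                   seed = 31L)
  cgnn <- cgnn_model(3L, 1L, types = 4L, node_feature_dim = 0L,
                     hidden_state = 4L, activation = "relu", K = 6L,
                     seed = 31L)
  cgnn$params$f[["4"]] <- gnn$params$f
  cgnn$params$out <- gnn$params$out
  b_plain <- batch_graphs(gs_raw)
  b_typed <- batch_graphs(lapply(gs_raw, heterogenize))
  expect_identical(unclass(propagate(b_plain, gnn)),
                   unclass(propagate(b_typed, cgnn)))
  expect_identical(graph_output(b_plain, propagate(b_plain, gnn), gnn),
                   graph_output(b_typed, propagate(b_typed, cgnn), cgnn))
})

test_that("unregistered node types are rejected by name", {
  g <- heterogenize(molecular_graph(c("C", "S"), rbind(c(1L, 2L)),
                                    targets = 1))
  m <- cgnn_model(2L, 1L, types = 4L, seed = 1L)
  expect_error(propagate(batch_graphs(list(g)), m), "type\\(s\\) 8")
})

test_that("graph outputs are invariant to node relabeling", {
  g <- rand_fixture_graph(6L, seed = 55L)
  m_g <- gnn_model(3L, 1L, node_feature_dim = 8L, K = 6L, seed = 9L)
  m_c <- cgnn_model(3L, 1L, K = 6L, seed = 9L)
  for (rep in 1:5) {
    perm <- withr::with_seed(rep, sample(6L))
    gp <- relabel_nodes(g, perm)
    b1 <- batch_graphs(list(homogenize(g)))
    b2 <- batch_graphs(list(homogenize(gp)))
    expect_equal(graph_output(b1, propagate(b1, m_g), m_g),
                 graph_output(b2, propagate(b2, m_g), m_g),
                 tolerance = 1e-6)
    h1 <- batch_graphs(list(heterogenize(g)))
    h2 <- batch_graphs(list(heterogenize(gp)))
    expect_equal(graph_output(h1, propagate(h1, m_c), m_c),
                 graph_output(h2, propagate(h2, m_c), m_c),
                 tolerance = 1e-6)
  }
})

test_that("graph outputs are independent of batch composition", {
  gs <- lapply(1:5, function(s) heterogenize(rand_fixture_graph(3L + s, s)))
  m <- cgnn_model(2L, 1L, hidden_state = 4L, K = 6L, seed = 14L)
  alone <- t(vapply(gs, function(g) {
    b <- batch_graphs(list(g))
    as.numeric(graph_output(b, propagate(b, m), m))
  }, numeric(1)))
  b_all <- batch_graphs(gs)
  together <- graph_output(b_all, propagate(b_all, m), m)
  expect_equal(as.numeric(alone), as.numeric(together), tolerance = 1e-6)
  # and inside a shuffled larger batch
  b_shuf <- batch_graphs(gs[c(3L, 1L, 5L, 2L, 4L)])
  shuf <- graph_output(b_shuf, propagate(b_shuf, m), m)
  expect_equal(as.numeric(shuf), as.numeric(together)[c(3L, 1L, 5L, 2L, 4L)],
               tolerance = 1e-6)
})
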