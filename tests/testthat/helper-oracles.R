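# Independent reference implementations used as oracles. Everything here is
# computed with explicit per-node / per-unit loops and its own activation
# closed forms, never through the package's vectorized forward pass.

ref_act <- function(name) {
  lambda <- 1.0507009873554805
  alpha <- 1.6732632423543772
  switch(name,
         relu = function(z) max(z, 0),
         tanh = function(z) tanh(z),
         selu = function(z) if (z > 0) lambda * z
           else lambda * alpha * (exp(z) - 1),
         sigmoid = function(z) 1 / (1 + exp(-z)))
}

# single-row MLP evaluation, unit by unit
ref_mlp_apply <- function(w, hidden_act, out_act, u) {
  h <- numeric(length(w$b1))
  for (j in seq_along(h)) {
    h[j] <- ref_act(hidden_act)(sum(u * w$W1[, j]) + w$b1[j])
  }
  o <- numeric(length(w$b2))
  for (k in seq_along(o)) {
    o[k] <- ref_act(out_act)(sum(h * w$W2[, k]) + w$b2[k])
  }
  o
}

# K-iteration propagation over a list of graphs by explicit neighbour loops;
# X0 is the initial state matrix for the disjoint union (rows in graph order)
ref_propagate <- function(model, graphs, X0) {
  offs <- c(0L, cumsum(vapply(graphs, n_nodes, integer(1))))
  X <- X0
  hidden <- model$f_spec$hidden_activation
  for (t in seq_len(model$prop$K)) {
    Xn <- X
    for (gi in seq_along(graphs)) {
      g <- graphs[[gi]]
      for (n in seq_len(n_nodes(g))) {
        row <- offs[gi] + n
        d_msg <- model$prop$state_dim +
          (if (model$include_neighbor_label) ncol(g$node_features) else 0L) +
          ncol(g$edge_features)
        msg <- numeric(d_msg)
        if (nrow(g$edges) > 0L) {
          for (e in seq_len(nrow(g$edges))) {
            pair <- g$edges[e, ]
            if (n %in% pair) {
              m <- setdiff(pair, n)
              piece <- X[offs[gi] + m, ]
              if (model$include_neighbor_label) {
                piece <- c(piece, g$node_features[m, ])
              }
              msg <- msg + c(piece, g$edge_features[e, ])
            }
          }
        }
        u <- c(X[row, ], g$node_features[n, ], msg)
        w <- if (model$kind == "cgnn") {
          model$params$f[[as.character(g$node_types[n])]]
        } else {
          model$params$f
        }
        Xn[row, ] <- ref_mlp_apply(w, hidden, hidden, u)
      }
    }
    X <- Xn
  }
  X
}

# graph-level outputs from final states, one graph at a time
ref_graph_output <- function(model, graphs, XK) {
  offs <- c(0L, cumsum(vapply(graphs, n_nodes, integer(1))))
  hidden <- model$out_spec$hidden_activation
  t(vapply(seq_along(graphs), function(gi) {
    g <- graphs[[gi]]
    per_node <- vapply(seq_len(n_nodes(g)), function(n)
      ref_mlp_apply(model$params$out, hidden, "sigmoid",
                    c(XK[offs[gi] + n, ], g$node_features[n, ])),
      numeric(model$n_tasks))
    if (model$n_tasks == 1L) mean(per_node)
    else rowMeans(matrix(per_node, nrow = model$n_tasks))
  }, numeric(model$n_tasks)))
}

# random small typed graph fixture (connected not required here)
rand_fixture_graph <- function(n, seed, n_targets = 1L, edge_p = 0.6,
                               elements = c("C", "N", "O", "S")) {
  withr::with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < edge_p
    molecular_graph(
      elements = sample(elements, n, replace = TRUE),
      edges = pairs[keep, , drop = FALSE],
      targets = stats::rbinom(n_targets, 1L, 0.5),
      graph_id = paste0("fix-", seed)
    )
  })
}

# small deterministic training fixture: binary label perfectly determined by
# the presence of oxygen, trivially separable
separable_fixture <- function(n_graphs = 8L, seed = 42L) {
  withr::with_seed(seed, {
    lapply(seq_len(n_graphs), function(i) {
      has_o <- i %% 2L == 0L
      els <- if (has_o) c("C", "O", "O") else c("C", "C", "N")
      molecular_graph(els, rbind(c(1L, 2L), c(2L, 3L)),
                      targets = as.numeric(has_o),
                      graph_id = paste0("sep-", i))
    })
  })
}
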