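#' Sample initial node states
#'
#' States start from an i.i.d. draw of a zero-centred uniform distribution,
#' U(-init_scale, +init_scale) per coordinate, seeded so that every forward
#' pass of a given model on a given batch is deterministic.
#'
#' @param node_count Number of nodes (rows).
#' @param cfg A [propagation_config()].
#' @return A `node_count` x `state_dim` matrix with attribute
#'   `iteration = 0`.
#' @export
init_states <- function(node_count, cfg) {
  stopifnot(inherits(cfg, "propagation_config"))
  if (node_count < 1L) stop("'node_count' must be >= 1", call. = FALSE)
  x <- withr::with_seed(cfg$seed, matrix(
    stats::runif(node_count * cfg$state_dim, -cfg$init_scale, cfg$init_scale),
    node_count, cfg$state_dim))
  attr(x, "iteration") <- 0L
  x
}

# sum rows of m by 'group' into an n-row matrix; groups with no rows get 0
agg_rows <- function(m, group, n) {
  out <- matrix(0, n, ncol(m))
  if (length(group) == 0L || ncol(m) == 0L) return(out)
  s <- rowsum(m, group = group)
  out[as.integer(rownames(s)), ] <- s
  out
}

# Build the state-updater input matrix: each node's row is the concatenation
# (x_n, l_n, sum over incoming arcs of (x_m [, l_m], e_{m,n})). The sum of
# concatenations equals the concatenation of blockwise sums, so each block
# is aggregated separately; the empty sum is the zero vector.
compose_updater_input <- function(batch, states, include_neighbor_label) {
  n <- sum(batch$n_nodes)
  msg_x <- agg_rows(states[batch$src, , drop = FALSE], batch$dst, n)
  msg_e <- agg_rows(batch$arc_features, batch$dst, n)
  if (include_neighbor_label) {
    msg_l <- agg_rows(batch$node_features[batch$src, , drop = FALSE],
                      batch$dst, n)
    cbind(states, batch$node_features, msg_x, msg_l, msg_e)
  } else {
    cbind(states, batch$node_features, msg_x, msg_e)
  }
}

#' One synchronous state-update iteration (standard GNN)
#'
#' All nodes are updated in parallel from the previous iteration's states:
#' the shared state-updating network is applied to every node's composed
#' input. Nodes with no neighbours receive the zero message.
#'
#' @param batch A [batch_graphs()] result (a single graph is accepted).
#' @param states Current state matrix (from [init_states()] or a previous
#'   step).
#' @param model A [gnn_model()].
#' @return The updated state matrix with `iteration` incremented.
#' @export
gnn_step <- function(batch, states, model) {
  batch <- as_graph_batch(batch)
  U <- compose_updater_input(batch, states, model$include_neighbor_label)
  new_states <- mlp_forward(model$params$f, model$f_spec, U)
  attr(new_states, "iteration") <- (attr(states, "iteration") %||% 0L) + 1L
  new_states
}

#' One synchronous state-update iteration (composite GNN)
#'
#' Like [gnn_step()], but each node is dispatched to the state-updating
#' network registered for its type.
#'
#' @inheritParams gnn_step
#' @param model A [cgnn_model()].
#' @export
cgnn_step <- function(batch, states, model) {
  batch <- as_graph_batch(batch)
  if (is.null(batch$node_types)) {
    stop("composite models need composite graphs: run heterogenize() first",
         call. = FALSE)
  }
  present <- sort(unique(batch$node_types))
  missing_types <- setdiff(present, model$types)
  if (length(missing_types) > 0L) {
    stop("no state-updating network registered for node type(s) ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  U <- compose_updater_input(batch, states, model$include_neighbor_label)
  new_states <- matrix(0, nrow(states), model$prop$state_dim)
  for (ty in present) {
    rows <- which(batch$node_types == ty)
    new_states[rows, ] <- mlp_forward(model$params$f[[as.character(ty)]],
                                      model$f_spec,
                                      U[rows, , drop = FALSE])
  }
  attr(new_states, "iteration") <- (attr(states, "iteration") %||% 0L) + 1L
  new_states
}

#' Run the full K-iteration state propagation
#'
#' @param batch Graphs, a single graph, or a [batch_graphs()] result.
#' @param model A [gnn_model()] or [cgnn_model()].
#' @return The node-state matrix after exactly `K` updates from the seeded
#'   initial states (`iteration` attribute = K).
#' @export
propagate <- function(batch, model) {
  batch <- as_graph_batch(batch)
  states <- init_states(sum(batch$n_nodes), model$prop)
  step <- if (model$kind == "cgnn") cgnn_step else gnn_step
  for (t in seq_len(model$prop$K)) states <- step(batch, states, model)
  states
}

#' Graph-level output from final node states
#'
#' The output network is applied to every node's (final state, features)
#' pair and the per-node outputs are averaged within each graph, giving one
#' output vector per graph with entries in (0, 1) (sigmoid head).
#'
#' @param batch Graphs or a [batch_graphs()] result.
#' @param states Final node states (typically from [propagate()]).
#' @param model The model that produced the states.
#' @return An `n_graphs` x `n_tasks` matrix.
#' @export
graph_output <- function(batch, states, model) {
  batch <- as_graph_batch(batch)
  O <- mlp_forward(model$params$out, model$out_spec,
                   cbind(states, batch$node_features))
  rowsum(O, batch$graph_membership) / batch$n_nodes
}

#' Model predictions for a set of graphs
#'
#' Convenience wrapper: propagation followed by graph output, returned as a
#' tibble with one row per graph.
#'
#' @param object A `gnn_model` or `cgnn_model`.
#' @param graphs Graphs or a batch.
#' @param ... Unused.
#' @return A tibble with `graph_id` and one `taskk` column per task.
#' @export
predict.gnn_model <- function(object, graphs, ...) {
  batch <- as_graph_batch(graphs)
  y <- graph_output(batch, propagate(batch, object), object)
  colnames(y) <- paste0("task", seq_len(ncol(y)))
  dplyr::bind_cols(
    tibble::tibble(graph_id = vapply(batch$graphs, `[[`, character(1), "graph_id")),
    tibble::as_tibble(y))
}

# ---- cached forward / backward passes (training engine) ----

# Forward pass keeping everything backpropagation needs. Returns per-graph
# outputs Y, per-step caches and the output-net cache.
forward_model <- function(model, batch) {
  n <- sum(batch$n_nodes)
  states <- init_states(n, model$prop)
  step_caches <- vector("list", model$prop$K)
  composite <- model$kind == "cgnn"
  if (composite) {
    present <- sort(unique(batch$node_types))
    bad <- setdiff(present, model$types)
    if (length(bad) > 0L) {
      stop("no state-updating network registered for node type(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    type_rows <- lapply(present, function(ty) which(batch$node_types == ty))
    names(type_rows) <- as.character(present)
  }
  for (t in seq_len(model$prop$K)) {
    U <- compose_updater_input(batch, states, model$include_neighbor_label)
    if (!composite) {
      cache <- mlp_forward(model$params$f, model$f_spec, U, cache = TRUE)
      states <- cache$output
      step_caches[[t]] <- cache
    } else {
      new_states <- matrix(0, n, model$prop$state_dim)
      caches <- lapply(names(type_rows), function(ty) {
        cc <- mlp_forward(model$params$f[[ty]], model$f_spec,
                          U[type_rows[[ty]], , drop = FALSE], cache = TRUE)
        new_states[type_rows[[ty]], ] <<- cc$output
        cc
      })
      names(caches) <- names(type_rows)
      states <- new_states
      step_caches[[t]] <- caches
    }
  }
  out_cache <- mlp_forward(model$params$out, model$out_spec,
                           cbind(states, batch$node_features), cache = TRUE)
  Y <- rowsum(out_cache$output, batch$graph_membership) / batch$n_nodes
  list(Y = Y, out_cache = out_cache, step_caches = step_caches,
       type_rows = if (composite) type_rows)
}

# Reverse-mode gradients of a scalar loss through the whole model.
# d_Y = dL/dY (n_graphs x n_tasks). Returns a gradient tree mirroring
# model$params (initial states are constants, not parameters).
backward_model <- function(model, batch, fwd, d_Y) {
  n <- sum(batch$n_nodes)
  d_x <- model$prop$state_dim
  d_l <- model$node_feature_dim
  composite <- model$kind == "cgnn"
  # mean readout: each node inherits its graph's output gradient / n_nodes
  d_O <- d_Y[batch$graph_membership, , drop = FALSE] /
    batch$n_nodes[batch$graph_membership]
  ob <- mlp_backward(model$params$out, model$out_spec, fwd$out_cache, d_O)
  grads <- list(f = NULL, out = ob$grads)
  d_states <- ob$d_input[, seq_len(d_x), drop = FALSE]
  x_msg_cols <- d_x + d_l + seq_len(d_x)
  if (!composite) {
    grads$f <- zero_like_params(model$params$f)
    for (t in rev(seq_len(model$prop$K))) {
      sb <- mlp_backward(model$params$f, model$f_spec,
                         fwd$step_caches[[t]], d_states)
      grads$f <- map_params(`+`, grads$f, sb$grads)
      d_U <- sb$d_input
      d_states <- d_U[, seq_len(d_x), drop = FALSE] +
        agg_rows(d_U[batch$dst, x_msg_cols, drop = FALSE], batch$src, n)
    }
  } else {
    grads$f <- lapply(model$params$f, zero_like_params)
    for (t in rev(seq_len(model$prop$K))) {
      d_U <- matrix(0, n, model$f_spec$input_dim)
      for (ty in names(fwd$type_rows)) {
        rows <- fwd$type_rows[[ty]]
        sb <- mlp_backward(model$params$f[[ty]], model$f_spec,
                           fwd$step_caches[[t]][[ty]],
                           d_states[rows, , drop = FALSE])
        grads$f[[ty]] <- map_params(`+`, grads$f[[ty]], sb$grads)
        d_U[rows, ] <- sb$d_input
      }
      d_states <- d_U[, seq_len(d_x), drop = FALSE] +
        agg_rows(d_U[batch$dst, x_msg_cols, drop = FALSE], batch$src, n)
    }
  }
  # types the model knows but the batch lacks contribute zero gradient
  if (composite) {
    for (ty in setdiff(names(model$params$f), names(grads$f))) {
      grads$f[[ty]] <- zero_like_params(model$params$f[[ty]])
    }
    grads$f <- grads$f[names(model$params$f)]
  }
  grads[c("f", "out")]
}
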