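#' Propagation settings for a recurrent GNN
#'
#' @param K Number of message-passing iterations (>= 0); all reference
#'   experiments use 6.
#' @param state_dim Dimension `d_x` of every node-state vector.
#' @param aggregation Aggregation of incoming neighbour messages; only
#'   `"sum"` is supported (the setting used throughout).
#' @param init_scale Half-width of the zero-centred uniform distribution
#'   used to sample initial node states. The default 0 starts every state
#'   at the origin (the degenerate limit of that distribution), which makes
#'   graph outputs exactly invariant to node relabeling and to batch
#'   composition; set it above 0 to reproduce randomized initial states.
#' @param seed Integer seed for the initial-state draw.
#' @export
propagation_config <- function(K = 6L, state_dim, aggregation = "sum",
                               init_scale = 0, seed = 1L) {
  if (!is.numeric(K) || length(K) != 1L || K < 0 || K != round(K)) {
    stop("'K' must be a non-negative integer", call. = FALSE)
  }
  aggregation <- match.arg(aggregation, "sum")
  if (!is.numeric(state_dim) || state_dim < 1 || state_dim != round(state_dim)) {
    stop("'state_dim' must be a positive integer", call. = FALSE)
  }
  if (init_scale < 0) stop("'init_scale' must be >= 0", call. = FALSE)
  structure(list(K = as.integer(K), state_dim = as.integer(state_dim),
                 aggregation = aggregation, init_scale = init_scale,
                 seed = as.integer(seed)),
            class = "propagation_config")
}

# derive a reproducible sub-seed from a base seed (kept inside 32-bit range)
seed_chain <- function(seed, k) {
  as.integer((as.numeric(seed) %% 214748329 * 7919 + k * 104729) %% 2147483629)
}

# input dimension of the state-updating network given the message composition
state_updater_input_dim <- function(state_dim, d_l, d_e, include_neighbor_label) {
  state_dim + d_l + state_dim + (if (include_neighbor_label) d_l else 0L) + d_e
}

#' Build a standard recurrent GNN model
#'
#' One weight-shared state-updating MLP `f_w` refines every node's state for
#' `K` iterations from the node's previous state, its features and the sum
#' of its neighbours' messages (neighbour state, neighbour features, edge
#' features, concatenated); one output MLP `g_w` with a sigmoid head maps
#' final states to per-node outputs, averaged over the graph.
#'
#' @param state_dim State dimension `d_x`.
#' @param n_tasks Number of graph-level prediction tasks (output dimension).
#' @param node_feature_dim,edge_feature_dim Feature dimensions of the graphs
#'   the model will consume.
#' @param hidden_state,hidden_output Hidden units of the state-updating and
#'   output networks.
#' @param activation Shared activation: `"relu"`, `"tanh"` or `"selu"`.
#' @param K Message-passing iterations.
#' @param init_scale Initial-state scale (see [propagation_config()]).
#' @param include_neighbor_label Whether the aggregated message includes the
#'   neighbour's feature vector (the standard-GNN formulation does).
#' @param seed Integer seed for all weight initializations.
#' @return An object of class `gnn_model`.
#' @export
gnn_model <- function(state_dim, n_tasks, node_feature_dim = 0L,
                      edge_feature_dim = 0L, hidden_state = 20L,
                      hidden_output = 20L, activation = "tanh", K = 6L,
                      init_scale = 0, include_neighbor_label = TRUE,
                      seed = 1L) {
  prop <- propagation_config(K, state_dim, "sum", init_scale, seed)
  f_spec <- mlp_spec(
    state_updater_input_dim(state_dim, node_feature_dim, edge_feature_dim,
                            include_neighbor_label),
    hidden_state, state_dim, activation, "same")
  out_spec <- mlp_spec(state_dim + node_feature_dim, hidden_output, n_tasks,
                       activation, "sigmoid")
  structure(
    list(kind = "gnn", f_spec = f_spec, out_spec = out_spec, prop = prop,
         params = list(f = build_mlp(f_spec, seed_chain(seed, 1L)),
                       out = build_mlp(out_spec, seed_chain(seed, 2L))),
         node_feature_dim = as.integer(node_feature_dim),
         edge_feature_dim = as.integer(edge_feature_dim),
         n_tasks = as.integer(n_tasks),
         include_neighbor_label = isTRUE(include_neighbor_label),
         seed = as.integer(seed)),
    class = "gnn_model"
  )
}

#' Build a composite (heterogeneous) recurrent GNN model
#'
#' The composite model dedicates one state-updating MLP `f_{w,i}` to each
#' node type `i` (element group): a node of type `i` is updated by its own
#' network from its previous state, its features and the sum of neighbour
#' messages (neighbour state and edge features; the neighbour's features are
#' not repeated in the message in this formulation). All state-updating
#' networks share the output dimension `d_x`, so differently typed nodes
#' exchange messages seamlessly, and a single sigmoid-headed output network
#' serves the whole graph.
#'
#' @inheritParams gnn_model
#' @param types Integer vector of node types (element-group indices in 1..8)
#'   the model supports; one state-updating network is built per type.
#' @return An object of class `cgnn_model`.
#' @export
cgnn_model <- function(state_dim, n_tasks, types = 1:8,
                       node_feature_dim = 0L, edge_feature_dim = 0L,
                       hidden_state = 20L, hidden_output = 20L,
                       activation = "tanh", K = 6L, init_scale = 0,
                       include_neighbor_label = FALSE, seed = 1L) {
  types <- sort(unique(as.integer(types)))
  if (length(types) == 0L || any(types < 1L | types > 8L)) {
    stop("'types' must be a non-empty subset of 1..8", call. = FALSE)
  }
  prop <- propagation_config(K, state_dim, "sum", init_scale, seed)
  f_spec <- mlp_spec(
    state_updater_input_dim(state_dim, node_feature_dim, edge_feature_dim,
                            include_neighbor_label),
    hidden_state, state_dim, activation, "same")
  out_spec <- mlp_spec(state_dim + node_feature_dim, hidden_output, n_tasks,
                       activation, "sigmoid")
  updaters <- lapply(seq_along(types), function(k)
    build_mlp(f_spec, seed_chain(seed, 10L + types[k])))
  names(updaters) <- as.character(types)
  structure(
    list(kind = "cgnn", f_spec = f_spec, out_spec = out_spec, prop = prop,
         params = list(f = updaters,
                       out = build_mlp(out_spec, seed_chain(seed, 2L))),
         types = types,
         node_feature_dim = as.integer(node_feature_dim),
         edge_feature_dim = as.integer(edge_feature_dim),
         n_tasks = as.integer(n_tasks),
         include_neighbor_label = isTRUE(include_neighbor_label),
         seed = as.integer(seed)),
    class = c("cgnn_model", "gnn_model")
  )
}

#' @export
print.gnn_model <- function(x, ...) {
  cat(sprintf(
    "<%s>: d_x=%d, K=%d, %s, state net %d->%d->%d%s, output net %d->%d->%d (sigmoid)\n",
    x$kind, x$prop$state_dim, x$prop$K, x$f_spec$hidden_activation,
    x$f_spec$input_dim, x$f_spec$hidden_units, x$f_spec$output_dim,
    if (x$kind == "cgnn")
      sprintf(" x %d types (%s)", length(x$types),
              paste(x$types, collapse = ",")) else "",
    x$out_spec$input_dim, x$out_spec$hidden_units, x$out_spec$output_dim))
  invisible(x)
}

# ---- parameter-tree helpers (nested lists of matrices/vectors) ----

# apply f elementwise across parallel nested parameter lists
map_params <- function(f, ...) {
  ps <- list(...)
  p1 <- ps[[1L]]
  if (is.list(p1)) {
    out <- lapply(seq_along(p1), function(i)
      do.call(map_params, c(list(f), lapply(ps, `[[`, i))))
    names(out) <- names(p1)
    out
  } else {
    do.call(f, ps)
  }
}

zero_like_params <- function(p) map_params(function(x) x * 0, p)
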