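#' Construct a molecular graph
#'
#' A molecular graph is an undirected graph whose nodes are atoms labelled
#' with chemical-element symbols, optionally carrying extra per-node feature
#' vectors, per-edge feature vectors (e.g. bond descriptors) and a vector of
#' graph-level targets (one per prediction task; `NA` marks a missing label).
#'
#' Edges are undirected bonds: self-loops and duplicate edges are rejected.
#' Node indices are 1-based.
#'
#' @param elements Character vector of element symbols, one per node.
#' @param edges Two-column integer matrix (or data frame) of undirected
#'   edges; may have zero rows.
#' @param node_features Numeric matrix with one row per node (default: zero
#'   columns — the element symbol is the only node information).
#' @param edge_features Numeric matrix with one row per edge (default: zero
#'   columns).
#' @param targets Numeric vector of graph-level targets; `NA` = missing.
#' @param graph_id Identifier string.
#' @return An object of class `molecular_graph`.
#' @examples
#' g <- molecular_graph(c("C", "C", "O"), rbind(c(1, 2), c(2, 3)),
#'                      targets = 1, graph_id = "ethanol-skeleton")
#' g
#' @export
molecular_graph <- function(elements, edges = matrix(integer(), 0, 2),
                            node_features = NULL, edge_features = NULL,
                            targets = numeric(), graph_id = "g") {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecular graph needs at least one node", call. = FALSE)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), 0L, 2L)
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  if (ncol(edges) != 2L) stop("'edges' must have two columns", call. = FALSE)
  if (nrow(edges) > 0L) {
    if (anyNA(edges) || any(edges < 1L) || any(edges > n)) {
      stop("graph '", graph_id, "': edge endpoint outside 1..", n,
           call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("graph '", graph_id, "': self-loops are not allowed",
           call. = FALSE)
    }
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) {
      stop("graph '", graph_id, "': duplicate undirected edge", call. = FALSE)
    }
  }
  if (is.null(node_features)) node_features <- matrix(numeric(), n, 0L)
  node_features <- as.matrix(node_features)
  dimnames(node_features) <- NULL
  storage.mode(node_features) <- "double"
  if (nrow(node_features) != n) {
    stop("graph '", graph_id, "': node_features must have one row per node",
         call. = FALSE)
  }
  if (is.null(edge_features)) {
    edge_features <- matrix(numeric(), nrow(edges), 0L)
  }
  edge_features <- as.matrix(edge_features)
  dimnames(edge_features) <- NULL
  storage.mode(edge_features) <- "double"
  if (nrow(edge_features) != nrow(edges)) {
    stop("graph '", graph_id, "': edge_features must have one row per edge",
         call. = FALSE)
  }
  structure(
    list(graph_id = as.character(graph_id), elements = elements,
         edges = edges, node_features = node_features,
         edge_features = edge_features, targets = as.numeric(targets)),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<%s> '%s': %d nodes (%s), %d edges, %d node feature(s), %d task target(s)\n",
              class(x)[1L], x$graph_id, n_nodes(x),
              paste(utils::head(x$elements, 8L), collapse = ""),
              nrow(x$edges), ncol(x$node_features), length(x$targets)))
  invisible(x)
}

#' Number of nodes of a graph
#' @param g A `molecular_graph`.
#' @export
n_nodes <- function(g) length(g$elements)

#' Assign node types from element groups (heterogenize)
#'
#' Converts a homogeneous molecular graph into its composite (heterogeneous)
#' form: every node is assigned the type index of its element group. The
#' node features are left untouched and do not encode the species — the node
#' type carries that information, so each type's state-updating network can
#' specialize on it.
#'
#' @param g A [molecular_graph()].
#' @param grouping An [element_grouping()].
#' @return A `composite_graph` (subclass of `molecular_graph`) with fields
#'   `node_types` (per-node group index) and `per_type_index` (node indices
#'   of each of the 8 groups).
#' @examples
#' heterogenize(molecular_graph(c("C", "C", "O"), rbind(c(1, 2), c(2, 3))))
#' @export
heterogenize <- function(g, grouping = element_grouping()) {
  stopifnot(inherits(g, "molecular_graph"))
  types <- tryCatch(
    element_to_group(g$elements, grouping),
    error = function(e) {
      bad <- which(!g$elements %in% names(grouping$element_to_group))
      stop(conditionMessage(e), " (graph '", g$graph_id, "', node index ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  )
  g$node_types <- types
  g$per_type_index <- lapply(seq_len(8L), function(i) which(types == i))
  class(g) <- c("composite_graph", "molecular_graph")
  g
}

#' One-hot encode element groups into node features (homogenize)
#'
#' Converts a molecular graph into the homogeneous form consumed by a
#' standard GNN: each node's feature vector is its original features
#' concatenated with an 8-long one-hot encoding of its element group. The
#' graph structure and targets are unchanged.
#'
#' @inheritParams heterogenize
#' @return A `molecular_graph` with 8 extra node-feature columns.
#' @examples
#' homogenize(molecular_graph("S"))$node_features
#' @export
homogenize <- function(g, grouping = element_grouping()) {
  stopifnot(inherits(g, "molecular_graph"))
  types <- element_to_group(g$elements, grouping)
  if (any(types < 1L | types > 8L)) {
    stop("corrupted grouping: group index outside 1..8", call. = FALSE)
  }
  onehot <- matrix(0, n_nodes(g), 8L)
  onehot[cbind(seq_len(n_nodes(g)), types)] <- 1
  g$node_features <- cbind(g$node_features, onehot)
  g$node_types <- NULL
  g$per_type_index <- NULL
  class(g) <- "molecular_graph"
  g
}

#' Relabel the nodes of a graph by a permutation
#'
#' Mainly used to verify permutation invariance of graph-level outputs:
#' node `i` of the result is node `perm[i]` of the input.
#'
#' @param g A [molecular_graph()].
#' @param perm A permutation of `1:n_nodes(g)`.
#' @export
relabel_nodes <- function(g, perm) {
  stopifnot(inherits(g, "molecular_graph"),
            setequal(perm, seq_len(n_nodes(g))))
  inv <- order(perm) # inv[old] = new index
  out <- molecular_graph(
    elements = g$elements[perm],
    edges = matrix(inv[g$edges], ncol = 2L),
    node_features = g$node_features[perm, , drop = FALSE],
    edge_features = g$edge_features,
    targets = g$targets, graph_id = g$graph_id
  )
  if (inherits(g, "composite_graph")) out <- heterogenize_types(out, g$node_types[perm])
  out
}

# attach precomputed types (internal; used where the grouping is not at hand)
heterogenize_types <- function(g, types) {
  g$node_types <- as.integer(types)
  g$per_type_index <- lapply(seq_len(8L), function(i) which(types == i))
  class(g) <- c("composite_graph", "molecular_graph")
  g
}
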