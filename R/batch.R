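#' Batch graphs into a disjoint union
#'
#' Stacks a list of molecular graphs into one block-diagonal batch: node
#' indices are offset so that no edge crosses a graph boundary, node features
#' and targets are stacked, and each undirected bond is unrolled into two
#' directed arcs so that sum-aggregation over a node's neighbourhood visits
#' each neighbour once per direction.
#'
#' @param graphs Non-empty list of [molecular_graph()] (or `composite_graph`)
#'   objects with identical node/edge feature dimensions and task counts.
#' @return An object of class `graph_batch`.
#' @examples
#' b <- batch_graphs(list(molecular_graph(c("C", "O"), rbind(c(1, 2))),
#'                        molecular_graph("S")))
#' b$graph_membership
#' @export
batch_graphs <- function(graphs) {
  if (!is.list(graphs) || length(graphs) == 0L) {
    stop("'graphs' must be a non-empty list of molecular graphs",
         call. = FALSE)
  }
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  stopifnot(all(vapply(graphs, inherits, logical(1), "molecular_graph")))
  d_l <- vapply(graphs, function(g) ncol(g$node_features), integer(1))
  d_e <- vapply(graphs, function(g) ncol(g$edge_features), integer(1))
  n_t <- vapply(graphs, function(g) length(g$targets), integer(1))
  if (length(unique(d_l)) != 1L) {
    stop("graphs have differing node-feature dimensions: ",
         paste(unique(d_l), collapse = ", "), call. = FALSE)
  }
  if (length(unique(d_e)) != 1L) {
    stop("graphs have differing edge-feature dimensions", call. = FALSE)
  }
  if (length(unique(n_t)) != 1L) {
    stop("graphs have differing task counts", call. = FALSE)
  }
  composite <- vapply(graphs, inherits, logical(1), "composite_graph")
  if (any(composite) && !all(composite)) {
    stop("cannot mix composite and plain molecular graphs in one batch",
         call. = FALSE)
  }

  nn <- vapply(graphs, n_nodes, integer(1))
  offsets <- c(0L, cumsum(nn)[-length(nn)])
  n_total <- sum(nn)
  src <- integer(0); dst <- integer(0)
  arc_features <- matrix(numeric(), 0L, d_e[1L])
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    if (nrow(e) > 0L) {
      src <- c(src, e[, 1L] + offsets[i], e[, 2L] + offsets[i])
      dst <- c(dst, e[, 2L] + offsets[i], e[, 1L] + offsets[i])
      ef <- graphs[[i]]$edge_features
      arc_features <- rbind(arc_features, ef, ef)
    }
  }
  structure(
    list(graphs = graphs,
         n_graphs = length(graphs),
         n_nodes = nn,
         node_offsets = offsets,
         graph_membership = rep(seq_along(graphs), nn),
         node_features = do.call(rbind, lapply(graphs, `[[`, "node_features")),
         node_types = if (all(composite))
           unlist(lapply(graphs, `[[`, "node_types"), use.names = FALSE),
         src = src, dst = dst, arc_features = arc_features,
         targets = if (n_t[1L] > 0L)
           do.call(rbind, lapply(graphs, `[[`, "targets"))
         else matrix(numeric(), length(graphs), 0L),
         n_tasks = n_t[1L]),
    class = "graph_batch"
  )
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

#' @export
print.graph_batch <- function(x, ...) {
  cat(sprintf("<graph_batch>: %d graphs, %d nodes, %d arcs, %d task(s)%s\n",
              x$n_graphs, sum(x$n_nodes), length(x$src), x$n_tasks,
              if (!is.null(x$node_types)) " (composite)" else ""))
  invisible(x)
}

#' Recover the graphs of a batch
#'
#' @param batch A [batch_graphs()] result.
#' @return The original list of graphs, exactly as supplied.
#' @export
unbatch_graphs <- function(batch) {
  stopifnot(inherits(batch, "graph_batch"))
  batch$graphs
}

# coerce graphs / single graph to batch (internal convenience)
as_graph_batch <- function(x) {
  if (inherits(x, "graph_batch")) x
  else if (inherits(x, "molecular_graph")) batch_graphs(list(x))
  else batch_graphs(x)
}
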