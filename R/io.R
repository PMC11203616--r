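#' Write molecular graphs to the JSON dialect
#'
#' One file per dataset split: a top-level JSON array of graph records
#' `{id, elements, node_features, edges, edge_features, targets}`. Node
#' indices are 0-based on disk; missing targets are encoded as `null`.
#' A write/read round trip is lossless.
#'
#' @param graphs List of [molecular_graph()] objects.
#' @param path Output file path.
#' @export
write_graphs <- function(graphs, path) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  records <- lapply(graphs, function(g) {
    list(
      id = g$graph_id,
      elements = g$elements,
      node_features = unname(apply(g$node_features, 1L, as.numeric,
                                   simplify = FALSE)),
      edges = unname(apply(g$edges - 1L, 1L, as.integer, simplify = FALSE)),
      edge_features = unname(apply(g$edge_features, 1L, as.numeric,
                                   simplify = FALSE)),
      targets = as.list(g$targets)
    )
  })
  # 17 significant digits: doubles survive the write -> read round trip
  jsonlite::write_json(records, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = I(17))
  invisible(path)
}

#' Read molecular graphs
#'
#' @param path File (JSON dialect) or directory (OGB adapter layout).
#' @param format `"json"` for this package's dialect; `"ogb"` for the
#'   on-disk layout produced by the OGB Python package for molecular
#'   graph-property datasets.
#' @param ... Passed to the format reader (`keep_node_features` for the OGB
#'   adapter).
#' @return List of [molecular_graph()] objects (all invariants enforced).
#' @export
read_graphs <- function(path, format = c("json", "ogb"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such path: ", path, call. = FALSE)
  switch(format,
         json = read_graphs_json(path),
         ogb = read_graphs_ogb(path, ...))
}

read_graphs_json <- function(path) {
  records <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(records), function(i) {
    r <- records[[i]]
    id <- r$id %||% paste0("g", i)
    need <- c("elements", "edges", "targets")
    miss <- setdiff(need, names(r))
    if (length(miss) > 0L) {
      stop("record ", i, " ('", id, "'): missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    to_mat <- function(rows, n_expected) {
      if (length(rows) == 0L || length(rows[[1L]]) == 0L) {
        return(matrix(numeric(), n_expected, 0L))
      }
      m <- do.call(rbind, lapply(rows, as.numeric))
      dimnames(m) <- NULL
      m
    }
    n <- length(r$elements)
    edges <- if (length(r$edges) == 0L) matrix(integer(), 0L, 2L)
      else do.call(rbind, lapply(r$edges, as.integer)) + 1L
    molecular_graph(
      elements = unlist(r$elements),
      edges = edges,
      node_features = to_mat(r$node_features %||% list(), n),
      edge_features = to_mat(r$edge_features %||% list(), nrow(edges)),
      targets = vapply(r$targets, function(t)
        if (is.null(t)) NA_real_ else as.numeric(t), numeric(1)),
      graph_id = id
    )
  })
}

# element symbols indexed by atomic number (for the OGB atom encoding,
# whose first atom feature is Z - 1)
.periodic_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

# Reads the raw/ + (optional) split CSV layout that the OGB Python package
# leaves on disk for graph-property-prediction molecule datasets. Both .csv
# and .csv.gz are accepted. Atom features follow the OGB encoding: the
# first column is the atomic number minus one; remaining columns are kept
# only on request (the default representation is species-only). OGB stores
# each bond as two directed rows of edge.csv, which are collapsed back to
# one undirected edge.
read_graphs_ogb <- function(path, keep_node_features = FALSE) {
  raw_dir <- if (dir.exists(file.path(path, "raw"))) file.path(path, "raw")
    else path
  read_csv_maybe_gz <- function(stem, required = TRUE) {
    for (f in file.path(raw_dir, paste0(stem, c(".csv", ".csv.gz")))) {
      if (file.exists(f)) {
        return(as.matrix(utils::read.csv(f, header = FALSE)))
      }
    }
    if (required) stop("OGB layout: missing ", stem, ".csv[.gz] under ",
                       raw_dir, call. = FALSE)
    NULL
  }
  num_nodes <- as.integer(read_csv_maybe_gz("num-node-list"))
  num_edges <- as.integer(read_csv_maybe_gz("num-edge-list"))
  edge <- read_csv_maybe_gz("edge")
  node_feat <- read_csv_maybe_gz("node-feat")
  labels <- read_csv_maybe_gz("graph-label", required = FALSE)
  edge_feat <- read_csv_maybe_gz("edge-feat", required = FALSE)
  if (length(num_nodes) != length(num_edges)) {
    stop("OGB layout: num-node-list and num-edge-list disagree",
         call. = FALSE)
  }
  node_off <- c(0L, cumsum(num_nodes))
  edge_off <- c(0L, cumsum(num_edges))
  lapply(seq_along(num_nodes), function(i) {
    nodes <- (node_off[i] + 1L):(node_off[i + 1L])
    z <- as.integer(node_feat[nodes, 1L]) + 1L
    if (any(z < 1L | z > length(.periodic_symbols))) {
      stop("graph ", i, ": atomic number out of range", call. = FALSE)
    }
    arcs <- if (num_edges[i] > 0L) {
      a <- edge[(edge_off[i] + 1L):(edge_off[i + 1L]), , drop = FALSE] + 1L
      keep <- a[, 1L] < a[, 2L]
      list(edges = a[keep, , drop = FALSE], keep = keep)
    } else {
      list(edges = matrix(integer(), 0L, 2L), keep = logical(0))
    }
    ef <- if (!is.null(edge_feat) && num_edges[i] > 0L) {
      edge_feat[(edge_off[i] + 1L):(edge_off[i + 1L]), ,
                drop = FALSE][arcs$keep, , drop = FALSE]
    } else NULL
    molecular_graph(
      elements = .periodic_symbols[z],
      edges = arcs$edges,
      node_features = if (keep_node_features && ncol(node_feat) > 1L)
        node_feat[nodes, -1L, drop = FALSE] else NULL,
      edge_features = ef,
      targets = if (!is.null(labels)) as.numeric(labels[i, ]) else numeric(),
      graph_id = paste0("ogb-", i)
    )
  })
}
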