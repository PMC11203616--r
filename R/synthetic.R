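#' Specification of a synthetic molecule-like dataset
#'
#' The generator emulates the shape of heavy-atom molecular graphs: small
#' sparse connected graphs (random spanning tree plus extra edges up to a
#' target density) whose nodes carry element symbols drawn from the eight
#' periodic-table groups, and whose graph-level targets are a known, typed
#' function of the node composition. Because the planted rules depend on
#' node types, the datasets are informative test beds for comparing
#' type-specialized (composite) against homogeneous models.
#'
#' @param n_graphs Number of graphs.
#' @param node_count_range `(min, max)` nodes per graph (default 2-40,
#'   the molecule-like range).
#' @param edge_density Target fraction of the `n(n-1)/2` possible edges
#'   (never below the `n - 1` spanning-tree edges that keep the graph
#'   connected). Default 0.15, giving sparse, bond-like graphs.
#' @param group_probabilities Probability of each of the 8 element groups
#'   per node, in table order (Metals, Metalloids, Halogens, C, N, O, P, S).
#'   Default is a carbon-dominated organochemical mixture.
#' @param task `"binary"`, `"multitask"` or `"regression"`.
#' @param target_rule `"type-fraction"` (binary: label 1 iff the fraction
#'   of nodes of one group exceeds a threshold) or `"type-weighted-sum"`
#'   (regression: sum over nodes of a per-group weight).
#' @param rule_params Parameters of the rule: `group` + `threshold` for
#'   type-fraction (vectors for multitask), `weights` (8-vector) for
#'   type-weighted-sum.
#' @param noise_level Label-flip probability (binary) or Gaussian target
#'   noise SD (regression). Default 0.1.
#' @param seed Integer seed.
#' @export
fixture_spec <- function(n_graphs = 600L, node_count_range = c(2L, 40L),
                         edge_density = 0.15,
                         group_probabilities = c(0.02, 0.02, 0.06, 0.55,
                                                 0.12, 0.15, 0.03, 0.05),
                         task = c("regression", "binary", "multitask"),
                         target_rule = NULL, rule_params = NULL,
                         noise_level = 0.1, seed = 1L) {
  task <- match.arg(task)
  if (length(node_count_range) != 2L ||
      node_count_range[1L] < 1L ||
      node_count_range[2L] < node_count_range[1L]) {
    stop("degenerate node_count_range", call. = FALSE)
  }
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must lie in (0, 1]", call. = FALSE)
  }
  if (length(group_probabilities) != 8L || any(group_probabilities < 0)) {
    stop("group_probabilities must be 8 non-negative values", call. = FALSE)
  }
  group_probabilities <- group_probabilities / sum(group_probabilities)
  if (is.null(target_rule)) {
    target_rule <- if (task == "regression") "type-weighted-sum"
      else "type-fraction"
  }
  target_rule <- match.arg(target_rule,
                           c("type-fraction", "type-weighted-sum"))
  if (is.null(rule_params)) {
    rule_params <- switch(
      target_rule,
      # threshold near the expected oxygen fraction -> balanced classes
      "type-fraction" = if (task == "multitask")
        list(group = c(6L, 5L, 3L), threshold = c(0.15, 0.12, 0.06))
      else list(group = 6L, threshold = 0.15),
      "type-weighted-sum" = list(
        weights = c(1.2, 0.8, -1.0, 0.1, 0.6, -0.7, 1.5, -0.4))
    )
  }
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  structure(list(n_graphs = as.integer(n_graphs),
                 node_count_range = as.integer(node_count_range),
                 edge_density = edge_density,
                 group_probabilities = group_probabilities,
                 task = task, target_rule = target_rule,
                 rule_params = rule_params, noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# one representative element per group; the models only see the group
.group_representatives <- c("Na", "Si", "Cl", "C", "N", "O", "P", "S")

#' Noise-free target of a graph under a planted rule
#'
#' The pure labelling function used by [generate_graphs()] before noise is
#' applied; exposed so tests can recompute targets independently.
#'
#' @param g A [molecular_graph()].
#' @param rule `"type-fraction"` or `"type-weighted-sum"`.
#' @param rule_params See [fixture_spec()].
#' @param grouping An [element_grouping()].
#' @return Numeric target vector (one entry per task).
#' @export
label_oracle <- function(g, rule, rule_params,
                         grouping = element_grouping()) {
  types <- element_to_group(g$elements, grouping)
  switch(match.arg(rule, c("type-fraction", "type-weighted-sum")),
         "type-fraction" = {
           vapply(seq_along(rule_params$group), function(k)
             as.numeric(mean(types == rule_params$group[k]) >
                          rule_params$threshold[k]),
             numeric(1))
         },
         "type-weighted-sum" = sum(rule_params$weights[types]))
}

# connected random graph: random recursive spanning tree + extra edges
# sampled uniformly from the remaining pairs up to the target density
random_connected_edges <- function(n, density) {
  if (n == 1L) return(matrix(integer(), 0L, 2L))
  tree <- cbind(vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)),
                2:n)
  target <- max(n - 1L, round(density * n * (n - 1L) / 2))
  extra_needed <- min(target, n * (n - 1L) / 2) - (n - 1L)
  if (extra_needed > 0L) {
    all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    key <- paste(pmin(tree[, 1L], tree[, 2L]), pmax(tree[, 1L], tree[, 2L]))
    pool <- all_pairs[!paste(all_pairs[, 1L], all_pairs[, 2L]) %in% key, ,
                      drop = FALSE]
    pick <- pool[sample.int(nrow(pool), min(extra_needed, nrow(pool))), ,
                 drop = FALSE]
    tree <- rbind(tree, pick)
  }
  unname(tree)
}

#' Generate a synthetic dataset with 80/10/10 splits
#'
#' Graphs are drawn independently under the spec, targets are computed by
#' the planted rule plus noise, and the set is split 80% / 10% / 10% into
#' train / validation / test by graph. Everything is a deterministic
#' function of the spec (including its seed).
#'
#' @param spec A [fixture_spec()].
#' @param grouping An [element_grouping()].
#' @return A list with elements `train`, `valid`, `test` (lists of
#'   [molecular_graph()]) and the generating `spec`.
#' @export
generate_graphs <- function(spec, grouping = element_grouping()) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    graphs <- lapply(seq_len(spec$n_graphs), function(i) {
      n <- sample(seq(spec$node_count_range[1L], spec$node_count_range[2L]),
                  1L)
      types <- sample.int(8L, n, replace = TRUE,
                          prob = spec$group_probabilities)
      g <- molecular_graph(
        elements = .group_representatives[types],
        edges = random_connected_edges(n, spec$edge_density),
        graph_id = sprintf("syn-%05d", i))
      y <- label_oracle(g, spec$target_rule, spec$rule_params, grouping)
      # noise variates are drawn even at level 0 so datasets differing only
      # in noise_level share graphs and clean labels under one seed
      y <- if (spec$target_rule == "type-fraction") {
        flip <- stats::runif(length(y)) < spec$noise_level
        ifelse(flip, 1 - y, y)
      } else {
        y + stats::rnorm(length(y), sd = spec$noise_level)
      }
      g$targets <- as.numeric(y)
      g
    })
    perm <- sample.int(spec$n_graphs)
    n_train <- round(0.8 * spec$n_graphs)
    n_valid <- round(0.1 * spec$n_graphs)
    list(train = graphs[perm[seq_len(n_train)]],
         valid = graphs[perm[n_train + seq_len(n_valid)]],
         test = graphs[perm[(n_train + n_valid + 1L):spec$n_graphs]],
         spec = spec)
  })
}

#' Write a generated dataset to a directory in the JSON dialect
#'
#' Produces `train.json`, `valid.json`, `test.json` plus a `spec.json`
#' provenance record.
#'
#' @param dataset A [generate_graphs()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (split in c("train", "valid", "test")) {
    write_graphs(dataset[[split]], file.path(out_dir, paste0(split, ".json")))
  }
  jsonlite::write_json(unclass(dataset$spec),
                       file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
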