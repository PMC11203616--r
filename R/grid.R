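#' Enumerate a hyperparameter grid
#'
#' Builds the Cartesian product of the hyperparameter value lists in a
#' deterministic order (later axes vary fastest). The default value lists
#' are the reference grid — initial learning rate (ilr), hidden units of
#' the state-updating network (hs), hidden units of the output network
#' (ho), state dimension (sd) and activation function (af) — whose product
#' is 4 x 4 x 4 x 5 x 3 = 960 configurations per model kind.
#'
#' @param ilr,hs,ho,sd,af Value lists for each hyperparameter axis.
#' @param model_kind Optional `"gnn"`/`"cgnn"` column appended to every row.
#' @return A tibble with one row per configuration and a `config_id`
#'   column in enumeration order.
#' @examples
#' nrow(enumerate_grid()) # 960
#' @export
enumerate_grid <- function(ilr = c(1e-2, 1e-3, 1e-4, 1e-5),
                           hs = c(10L, 20L, 30L, 50L),
                           ho = c(20L, 40L, 70L, 100L),
                           sd = c(3L, 5L, 10L, 15L, 30L),
                           af = c("relu", "tanh", "selu"),
                           model_kind = NULL) {
  axes <- list(ilr = ilr, hs = hs, ho = ho, sd = sd, af = af)
  for (nm in names(axes)) {
    if (length(axes[[nm]]) == 0L) {
      stop("empty value list for hyperparameter '", nm, "'", call. = FALSE)
    }
  }
  grid <- tidyr::expand_grid(ilr = ilr, hs = hs, ho = ho, sd = sd, af = af)
  grid <- dplyr::mutate(grid, config_id = dplyr::row_number(),
                        .before = 1L)
  if (!is.null(model_kind)) {
    grid$model_kind <- match.arg(model_kind, c("gnn", "cgnn"))
  }
  grid
}

# build the model a grid row describes, for data with the given dimensions
model_from_config <- function(config, model_kind, n_tasks, node_feature_dim,
                              edge_feature_dim, types = 1:8, K = 6L,
                              seed = 1L) {
  if (model_kind == "gnn") {
    gnn_model(state_dim = config$sd, n_tasks = n_tasks,
              node_feature_dim = node_feature_dim,
              edge_feature_dim = edge_feature_dim,
              hidden_state = config$hs, hidden_output = config$ho,
              activation = config$af, K = K, seed = seed)
  } else {
    cgnn_model(state_dim = config$sd, n_tasks = n_tasks, types = types,
               node_feature_dim = node_feature_dim,
               edge_feature_dim = edge_feature_dim,
               hidden_state = config$hs, hidden_output = config$ho,
               activation = config$af, K = K, seed = seed)
  }
}

# representation the model kind consumes: one-hot homogenization for the
# standard GNN, typed heterogenization for the composite model
prepare_representation <- function(graphs, model_kind, grouping) {
  if (model_kind == "gnn") {
    lapply(graphs, homogenize, grouping = grouping)
  } else {
    lapply(graphs, heterogenize, grouping = grouping)
  }
}

#' Run a hyperparameter sweep
#'
#' Trains every configuration of the grid on the training split, scores it
#' on the validation split with the dataset's metric, selects the best
#' configuration (maximum for AUROC/AP, minimum for RMSE; ties break to the
#' earliest `config_id`) and finally evaluates the selected model on the
#' test split. Configurations that abort (e.g. a non-finite loss under an
#' aggressive learning rate) are recorded as failed and excluded from
#' selection. Each configuration trains under a seed derived from
#' `base_seed` and its `config_id`, so sweeps are reproducible and
#' parallelizable.
#'
#' @param splits List with `train`, `valid`, `test` lists of
#'   [molecular_graph()] objects (raw; representation is prepared per model
#'   kind).
#' @param grid An [enumerate_grid()] tibble with a `model_kind` column (or
#'   pass `model_kind`).
#' @param metric `"auroc"`, `"ap"` or `"rmse"`.
#' @param model_kind Used when the grid has no `model_kind` column.
#' @param grouping An [element_grouping()].
#' @param max_epochs,patience Training-protocol settings (defaults 300/10).
#' @param K Message-passing iterations (default 6).
#' @param base_seed Base seed for per-configuration seeding.
#' @return An object of class `sweep_result`.
#' @export
run_sweep <- function(splits, grid, metric = c("auroc", "ap", "rmse"),
                      model_kind = NULL, grouping = element_grouping(),
                      max_epochs = 300L, patience = 10L, K = 6L,
                      base_seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(all(c("train", "valid", "test") %in% names(splits)))
  if (is.null(grid$model_kind)) {
    if (is.null(model_kind)) {
      stop("supply 'model_kind' in the grid or as an argument",
           call. = FALSE)
    }
    grid$model_kind <- match.arg(model_kind, c("gnn", "cgnn"))
  }
  task_type <- if (metric == "rmse") "regression" else "binary"
  direction <- metric_direction(metric)
  kinds <- unique(grid$model_kind)
  reps <- lapply(stats::setNames(kinds, kinds), function(kind) {
    lapply(splits[c("train", "valid", "test")], prepare_representation,
           model_kind = kind, grouping = grouping)
  })
  n_tasks <- length(splits$train[[1L]]$targets)
  results <- vector("list", nrow(grid))
  best <- list(value = if (direction == "maximize") -Inf else Inf,
               fit = NULL, config_id = NA_integer_)
  for (i in seq_len(nrow(grid))) {
    config <- grid[i, ]
    rep_i <- reps[[config$model_kind]]
    seed_i <- seed_chain(base_seed, config$config_id)
    res <- tryCatch({
      model <- model_from_config(
        config, config$model_kind, n_tasks,
        node_feature_dim = ncol(rep_i$train[[1L]]$node_features),
        edge_feature_dim = ncol(rep_i$train[[1L]]$edge_features),
        types = sort(unique(unlist(lapply(splits$train, function(g)
          element_to_group(g$elements, grouping))))),
        K = K, seed = seed_i)
      fit <- fit_gnn(model, rep_i$train, rep_i$valid,
                     train_config(config$ilr, max_epochs, patience,
                                  task_type, seed = seed_i))
      val <- suppressWarnings(
        evaluate_model(fit, rep_i$valid, metric)$value)
      list(value = val, fit = fit, status = "ok", message = NA_character_)
    }, error = function(e) {
      list(value = NA_real_, fit = NULL, status = "failed",
           message = conditionMessage(e))
    })
    results[[i]] <- tibble::tibble(
      config_id = config$config_id, model_kind = config$model_kind,
      valid_value = res$value, status = res$status, message = res$message)
    better <- res$status == "ok" && is.finite(res$value) &&
      (if (direction == "maximize") res$value > best$value
       else res$value < best$value)
    if (better) {
      best <- list(value = res$value, fit = res$fit,
                   config_id = config$config_id,
                   model_kind = config$model_kind)
    }
  }
  results <- dplyr::left_join(grid, dplyr::bind_rows(results),
                              by = c("config_id", "model_kind"))
  if (is.null(best$fit)) stop("every configuration failed", call. = FALSE)
  test_rep <- reps[[best$model_kind]]$test
  test_value <- suppressWarnings(
    evaluate_model(best$fit, test_rep, metric)$value)
  structure(
    list(results = results, metric = metric, direction = direction,
         best_config_id = best$config_id,
         best_model_kind = best$model_kind,
         best_valid_value = best$value, best_fit = best$fit,
         test_value = test_value, base_seed = base_seed),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result>: %d configs, metric %s (%s); best config %d (%s), valid %.4f, test %.4f\n",
    nrow(x$results), x$metric, x$direction, x$best_config_id,
    x$best_model_kind, x$best_valid_value, x$test_value))
  invisible(x)
}
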