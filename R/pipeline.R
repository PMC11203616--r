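#' Save a fitted model as a portable text checkpoint
#'
#' Everything needed to rebuild the fit — model kind, architecture,
#' weights, normalizer and training configuration — is written as JSON at
#' full numeric precision.
#'
#' @param fit A [fit_gnn()] result.
#' @param path Output `.json` path.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "gnn_fit"))
  m <- fit$model
  payload <- list(
    kind = m$kind,
    arch = list(state_dim = m$prop$state_dim, K = m$prop$K,
                init_scale = m$prop$init_scale, seed = m$seed,
                n_tasks = m$n_tasks,
                node_feature_dim = m$node_feature_dim,
                edge_feature_dim = m$edge_feature_dim,
                hidden_state = m$f_spec$hidden_units,
                hidden_output = m$out_spec$hidden_units,
                activation = m$f_spec$hidden_activation,
                include_neighbor_label = m$include_neighbor_label,
                types = if (m$kind == "cgnn") m$types),
    params = map_params(identity, m$params),
    normalizer = if (!is.null(fit$normalizer)) unclass(fit$normalizer),
    config = unclass(fit$config),
    best_epoch = fit$best_epoch, stopped_epoch = fit$stopped_epoch)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load a checkpoint written by [write_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return A `gnn_fit` object (without the per-epoch record).
#' @export
read_checkpoint <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  a <- p$arch
  model <- if (p$kind == "gnn") {
    gnn_model(a$state_dim, a$n_tasks, a$node_feature_dim,
              a$edge_feature_dim, a$hidden_state, a$hidden_output,
              a$activation, a$K, a$init_scale, a$include_neighbor_label,
              a$seed)
  } else {
    cgnn_model(a$state_dim, a$n_tasks, a$types, a$node_feature_dim,
               a$edge_feature_dim, a$hidden_state, a$hidden_output,
               a$activation, a$K, a$init_scale, a$include_neighbor_label,
               a$seed)
  }
  # jsonlite returns row-major matrices back as matrices; vectors need care
  restore <- function(tmpl, got) {
    map_params(function(t, g) {
      if (is.matrix(t)) matrix(as.numeric(g), nrow(t), ncol(t), byrow = FALSE)
      else as.numeric(g)
    }, tmpl, got)
  }
  model$params <- restore(model$params, p$params)
  normalizer <- if (!is.null(p$normalizer)) {
    structure(list(min = as.numeric(p$normalizer$min),
                   max = as.numeric(p$normalizer$max)),
              class = "target_normalizer")
  }
  cfg <- train_config(p$config$initial_learning_rate, p$config$max_epochs,
                      p$config$patience, p$config$task_type, p$config$seed)
  structure(list(model = model, record = NULL,
                 best_epoch = p$best_epoch, stopped_epoch = p$stopped_epoch,
                 best_valid_loss = NA_real_, restored = NA,
                 normalizer = normalizer, config = cfg),
            class = "gnn_fit")
}

# ---- run configuration files (flat JSON, fail-fast) ----

.run_config_required <- c("model_kind", "ilr", "hs", "ho", "sd", "af")
.run_config_optional <- c("k", "max_epochs", "patience", "seed", "metric",
                          "init_scale")

#' Read and validate a flat run-configuration file
#'
#' The key set mirrors the grid axes plus the fixed training protocol:
#' required `model_kind, ilr, hs, ho, sd, af`; optional `k` (default 6),
#' `max_epochs` (300), `patience` (10), `seed` (1), `metric` ("auroc"),
#' `init_scale` (0.1). Unknown keys are errors, not warnings.
#'
#' @param config Path to a JSON file, or an equivalent named list.
#' @return Validated named list with defaults filled in.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) {
    jsonlite::fromJSON(config, simplifyVector = TRUE)
  } else {
    config
  }
  unknown <- setdiff(names(cfg), c(.run_config_required,
                                   .run_config_optional))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_keys <- setdiff(.run_config_required, names(cfg))
  if (length(missing_keys) > 0L) {
    stop("missing config key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(k = 6L, max_epochs = 300L, patience = 10L, seed = 1L,
                   metric = "auroc", init_scale = 0)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg$model_kind <- match.arg(cfg$model_kind, c("gnn", "cgnn"))
  cfg$metric <- match.arg(cfg$metric, c("auroc", "ap", "rmse"))
  cfg
}

run_manifest <- function(command, config, seeds, inputs, outputs) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  list(command = command, config = config, seeds = seeds,
       input_digests = digests, outputs = outputs,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version = as.character(utils::packageVersion("compgnn")))
}

read_dataset_dir <- function(dataset_path) {
  files <- file.path(dataset_path, paste0(c("train", "valid", "test"),
                                          ".json"))
  if (!all(file.exists(files))) {
    stop("dataset directory must contain train.json, valid.json, test.json",
         call. = FALSE)
  }
  stats::setNames(lapply(files, read_graphs), c("train", "valid", "test"))
}

#' Train one configuration end to end
#'
#' Loads a JSON-dialect dataset directory, prepares the representation the
#' model kind consumes (one-hot homogenization for `gnn`, typed
#' heterogenization for `cgnn`), trains with early stopping, evaluates on
#' the test split and writes `checkpoint.json`, `record.csv`,
#' `evaluation.json` and `manifest.json` under `out_dir`.
#'
#' @param dataset_path Directory with `train.json`, `valid.json`,
#'   `test.json`.
#' @param model_kind `"gnn"` or `"cgnn"` (overrides the config key).
#' @param config Path to a run-config JSON file or a named list (see
#'   [read_run_config()]).
#' @param out_dir Output directory.
#' @param grouping An [element_grouping()].
#' @return The run manifest, invisibly.
#' @export
cmd_train <- function(dataset_path, model_kind = NULL, config, out_dir,
                      grouping = element_grouping()) {
  cfg <- read_run_config(config)
  if (!is.null(model_kind)) {
    cfg$model_kind <- match.arg(model_kind, c("gnn", "cgnn"))
  }
  splits <- read_dataset_dir(dataset_path)
  reps <- lapply(splits, prepare_representation,
                 model_kind = cfg$model_kind, grouping = grouping)
  task_type <- if (cfg$metric == "rmse") "regression" else "binary"
  model <- model_from_config(
    list(sd = cfg$sd, hs = cfg$hs, ho = cfg$ho, af = cfg$af),
    cfg$model_kind, n_tasks = length(splits$train[[1L]]$targets),
    node_feature_dim = ncol(reps$train[[1L]]$node_features),
    edge_feature_dim = ncol(reps$train[[1L]]$edge_features),
    types = sort(unique(unlist(lapply(splits$train, function(g)
      element_to_group(g$elements, grouping))))),
    K = cfg$k, seed = cfg$seed)
  fit <- fit_gnn(model, reps$train, reps$valid,
                 train_config(cfg$ilr, cfg$max_epochs, cfg$patience,
                              task_type, seed = cfg$seed))
  report <- suppressWarnings(evaluate_model(fit, reps$test, cfg$metric))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("checkpoint.json", "record.csv",
                                "evaluation.json", "manifest.json"))
  write_checkpoint(fit, paths[1L])
  utils::write.csv(fit$record, paths[2L], row.names = FALSE)
  jsonlite::write_json(
    list(dataset = dataset_path, model_kind = cfg$model_kind,
         config_id = NA, metric = report$metric, value = report$value,
         n_examples = report$n_examples,
         per_task = report$per_task[[1L]],
         best_epoch = fit$best_epoch, stopped_epoch = fit$stopped_epoch),
    paths[3L], auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- run_manifest(
    "train", cfg, seeds = cfg$seed,
    inputs = file.path(dataset_path,
                       c("train.json", "valid.json", "test.json")),
    outputs = paths)
  jsonlite::write_json(manifest, paths[4L], auto_unbox = TRUE, digits = NA)
  message(sprintf("train: %s %s=%.4f (best epoch %d/%d)", cfg$model_kind,
                  report$metric, report$value, fit$best_epoch,
                  fit$stopped_epoch))
  invisible(manifest)
}

#' Re-evaluate a checkpoint on a dataset split (no training)
#'
#' @param checkpoint Path to a [write_checkpoint()] file.
#' @param dataset_path Dataset directory (JSON dialect).
#' @param out_dir Output directory for `evaluation.json` + `manifest.json`.
#' @param split Which split to score (default `"test"`).
#' @param metric Metric override; defaults to `"rmse"` for regression
#'   checkpoints and `"auroc"` otherwise.
#' @param grouping An [element_grouping()].
#' @return The evaluation report tibble, invisibly.
#' @export
cmd_evaluate <- function(checkpoint, dataset_path, out_dir,
                         split = c("test", "valid", "train"),
                         metric = NULL, grouping = element_grouping()) {
  split <- match.arg(split)
  fit <- read_checkpoint(checkpoint)
  graphs <- read_graphs(file.path(dataset_path, paste0(split, ".json")))
  if (is.null(metric)) {
    metric <- if (fit$config$task_type == "regression") "rmse" else "auroc"
  }
  rep_graphs <- prepare_representation(graphs, fit$model$kind, grouping)
  report <- suppressWarnings(evaluate_model(fit, rep_graphs, metric))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(out_dir, c("evaluation.json", "manifest.json"))
  jsonlite::write_json(
    list(dataset = dataset_path, split = split, metric = report$metric,
         value = report$value, n_examples = report$n_examples,
         per_task = report$per_task[[1L]]),
    out[1L], auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- run_manifest("evaluate", list(split = split),
                           seeds = fit$config$seed,
                           inputs = c(checkpoint,
                                      file.path(dataset_path,
                                                paste0(split, ".json"))),
                           outputs = out)
  jsonlite::write_json(manifest, out[2L], auto_unbox = TRUE, digits = NA)
  message(sprintf("evaluate [%s]: %s=%.4f", split, report$metric,
                  report$value))
  invisible(report)
}
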