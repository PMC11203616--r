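#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a uniformly chosen
#' positive example receives a higher score than a uniformly chosen negative
#' one, with tied pairs counted half. Missing labels (`NA`) are dropped. A
#' random scorer is expected to land at 0.5; a perfect ranker at 1.
#'
#' @param scores Numeric vector of scores (any monotone scale).
#' @param labels Binary vector in `{0, 1}` (`NA` = missing).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auroc <- function(scores, labels) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n_pos <- as.numeric(sum(labels == 1)) # doubles: pair counts overflow int
  n_neg <- as.numeric(sum(labels == 0))
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties as half-credit
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Multi-task AUROC
#'
#' Per-task AUROC averaged over the tasks whose evaluation labels contain
#' both classes; single-class tasks are dropped with a warning (there is
#' nothing to rank against).
#'
#' @param scores,labels Matrices (examples x tasks); `NA` labels excluded
#'   per task.
#' @return Named list with the mean `value` and `per_task` values (`NA` for
#'   dropped tasks).
#' @export
auroc_multitask <- function(scores, labels) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  per_task <- vapply(seq_len(ncol(labels)), function(j) {
    lab <- labels[, j]
    ok <- !is.na(lab)
    if (length(unique(lab[ok])) < 2L) return(NA_real_)
    auroc(scores[ok, j], lab[ok])
  }, numeric(1))
  if (all(is.na(per_task))) {
    stop("no task with both classes present", call. = FALSE)
  }
  if (anyNA(per_task)) {
    warning(sum(is.na(per_task)),
            " single-class task(s) dropped from the AUROC mean")
  }
  list(value = mean(per_task, na.rm = TRUE), per_task = per_task)
}

#' Average precision over parallel binary tasks
#'
#' For each task, precision is evaluated at the rank of every positive
#' example (descending score order) and averaged over the positives; the
#' per-task values are then averaged over tasks that contain at least one
#' positive. Missing labels are excluded.
#'
#' @param scores,labels Matrices or vectors (examples x tasks).
#' @return Named list with mean `value` and `per_task` values.
#' @export
average_precision <- function(scores, labels) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  ap_one <- function(s, y) {
    ok <- !is.na(y)
    s <- s[ok]; y <- y[ok]
    if (sum(y == 1) == 0L) return(NA_real_)
    ord <- order(-s)
    y <- y[ord]
    hits <- cumsum(y == 1)
    prec_at_pos <- hits[y == 1] / which(y == 1)
    mean(prec_at_pos)
  }
  per_task <- vapply(seq_len(ncol(labels)), function(j)
    ap_one(scores[, j], labels[, j]), numeric(1))
  if (all(is.na(per_task))) {
    stop("average precision undefined: no positives in any task",
         call. = FALSE)
  }
  list(value = mean(per_task, na.rm = TRUE), per_task = per_task)
}

#' Root mean squared error
#'
#' @param predictions,targets Numeric vectors of equal length (raw target
#'   units).
#' @return Non-negative scalar.
#' @export
rmse <- function(predictions, targets) {
  if (length(predictions) != length(targets)) {
    stop("predictions and targets must have equal length", call. = FALSE)
  }
  ok <- !is.na(targets)
  sqrt(mean((predictions[ok] - targets[ok])^2))
}

#' Evaluation metric used by each benchmark dataset
#'
#' Mirrors the metric assignment of the OGB molecular benchmark: every
#' binary-classification set is scored by AUROC except the heavily
#' imbalanced MUV (average precision); the one regression set, FreeSolv,
#' is scored by RMSE.
#'
#' @param dataset_name Dataset name, with or without the `ogbg-mol` prefix
#'   (case-insensitive): HIV, FreeSolv, Tox-21, BACE, BBBP, ClinTox, MUV,
#'   Sider.
#' @return One of `"auroc"`, `"ap"`, `"rmse"`.
#' @examples
#' metric_for_dataset("FreeSolv")
#' @export
metric_for_dataset <- function(dataset_name) {
  key <- gsub("[^a-z0-9]", "", tolower(sub("^ogbg-mol", "",
                                           tolower(dataset_name))))
  table <- c(hiv = "auroc", tox21 = "auroc", bace = "auroc",
             bbbp = "auroc", clintox = "auroc", sider = "auroc",
             freesolv = "rmse", muv = "ap")
  if (!key %in% names(table)) {
    stop("unknown dataset: ", dataset_name, call. = FALSE)
  }
  unname(table[[key]])
}

#' Direction in which a metric improves
#' @param metric `"auroc"`, `"ap"` or `"rmse"`.
#' @return `"maximize"` or `"minimize"`.
#' @export
metric_direction <- function(metric) {
  switch(match.arg(metric, c("auroc", "ap", "rmse")),
         auroc = "maximize", ap = "maximize", rmse = "minimize")
}

#' Score a fitted model on a set of graphs
#'
#' Computes the dataset metric from the fitted model's predictions:
#' AUROC / AP on the raw binary targets, or RMSE on the original regression
#' scale (predictions pass back through the stored normalizer).
#'
#' @param fit A [fit_gnn()] result.
#' @param graphs Graphs or a batch with targets.
#' @param metric `"auroc"`, `"ap"` or `"rmse"`.
#' @return A one-row tibble (`metric`, `value`, `n_examples`, `n_tasks`)
#'   with per-task values in the `per_task` list-column where applicable.
#' @export
evaluate_model <- function(fit, graphs, metric = c("auroc", "ap", "rmse")) {
  metric <- match.arg(metric)
  stopifnot(inherits(fit, "gnn_fit"))
  batch <- as_graph_batch(graphs)
  if (batch$n_tasks != fit$model$n_tasks) {
    stop("checkpoint predicts ", fit$model$n_tasks,
         " task(s) but dataset has ", batch$n_tasks, call. = FALSE)
  }
  if ((metric == "rmse") != (fit$config$task_type == "regression")) {
    stop("metric '", metric, "' does not match the fitted task type '",
         fit$config$task_type, "'", call. = FALSE)
  }
  cols <- paste0("task", seq_len(fit$model$n_tasks))
  pred <- as.matrix(predict(fit, batch)[cols])
  y <- batch$targets
  res <- switch(metric,
                auroc = auroc_multitask(pred, y),
                ap = average_precision(pred, y),
                rmse = list(value = rmse(as.vector(pred), as.vector(y)),
                            per_task = NULL))
  tibble::tibble(metric = metric, value = res$value,
                 n_examples = batch$n_graphs, n_tasks = batch$n_tasks,
                 per_task = list(res$per_task))
}
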