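#' Masked multi-task loss
#'
#' Binary multi-task problems use mean binary cross-entropy over the
#' observed (non-missing) prediction/target pairs only; regression uses
#' mean squared error on normalized targets. Missing targets (`NA`)
#' contribute nothing to the value or the gradient, which is what
#' non-mutually-exclusive multi-task label sets require.
#'
#' @param predictions `n_graphs` x `n_tasks` matrix of model outputs in
#'   (0, 1).
#' @param targets Matrix of the same shape; `NA` marks a missing label.
#' @param task_type `"binary"` (multi-task binary cross-entropy) or
#'   `"regression"` (mean squared error).
#' @return Scalar loss.
#' @export
masked_loss <- function(predictions, targets,
                        task_type = c("binary", "regression")) {
  task_type <- match.arg(task_type)
  predictions <- as.matrix(predictions); targets <- as.matrix(targets)
  if (!all(dim(predictions) == dim(targets))) {
    stop("predictions and targets must have identical shapes", call. = FALSE)
  }
  obs <- !is.na(targets)
  if (!any(obs)) stop("degenerate batch: all target entries missing",
                      call. = FALSE)
  p <- predictions[obs]; y <- targets[obs]
  if (task_type == "binary") {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((p - y)^2)
  }
}

# dL/d(predictions) of masked_loss; zero at missing entries
masked_loss_grad <- function(predictions, targets, task_type) {
  obs <- !is.na(targets)
  n_obs <- sum(obs)
  g <- matrix(0, nrow(predictions), ncol(predictions))
  p <- predictions[obs]; y <- targets[obs]
  if (task_type == "binary") {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    g[obs] <- (p - y) / (p * (1 - p)) / n_obs
  } else {
    g[obs] <- 2 * (p - y) / n_obs
  }
  g
}

#' Min-max target normalizer for regression tasks
#'
#' The sigmoid output head constrains predictions to (0, 1), so regression
#' targets are affinely mapped into [0, 1] using the training-split minimum
#' and maximum per task; the stored inverse restores the original scale at
#' evaluation time (RMSE is always reported on raw targets).
#'
#' @param train_targets Matrix (or vector) of training-split targets.
#' @return An object of class `target_normalizer` with `transform()` and
#'   `inverse()` applied via [normalize_apply()] / [normalize_invert()].
#' @export
normalize_targets <- function(train_targets) {
  y <- as.matrix(train_targets)
  mins <- apply(y, 2L, min, na.rm = TRUE)
  maxs <- apply(y, 2L, max, na.rm = TRUE)
  if (any(!is.finite(mins)) || any(!is.finite(maxs)) || any(maxs <= mins)) {
    stop("each regression task needs at least two distinct finite target values",
         call. = FALSE)
  }
  structure(list(min = mins, max = maxs), class = "target_normalizer")
}

#' @rdname normalize_targets
#' @param normalizer A `target_normalizer`.
#' @param targets Matrix of raw targets.
#' @export
normalize_apply <- function(normalizer, targets) {
  y <- as.matrix(targets)
  sweep(sweep(y, 2L, normalizer$min, `-`), 2L,
        normalizer$max - normalizer$min, `/`)
}

#' @rdname normalize_targets
#' @param normalized Matrix of normalized values.
#' @export
normalize_invert <- function(normalizer, normalized) {
  y <- as.matrix(normalized)
  sweep(sweep(y, 2L, normalizer$max - normalizer$min, `*`), 2L,
        normalizer$min, `+`)
}

#' Training configuration
#'
#' @param initial_learning_rate Adam's initial learning rate (the only
#'   searched optimizer hyperparameter).
#' @param max_epochs Hard epoch cap (default 300).
#' @param patience Early-stopping patience in epochs (default 10): training
#'   stops after this many consecutive epochs without a strict improvement
#'   of the validation loss, and the best-epoch weights are restored.
#' @param task_type `"binary"` or `"regression"`.
#' @param seed Integer seed controlling every random draw of the run.
#' @export
train_config <- function(initial_learning_rate = 1e-3, max_epochs = 300L,
                         patience = 10L,
                         task_type = c("binary", "regression"), seed = 1L) {
  task_type <- match.arg(task_type)
  if (patience < 1L) stop("'patience' must be >= 1", call. = FALSE)
  if (max_epochs < 1L) stop("'max_epochs' must be >= 1", call. = FALSE)
  structure(list(initial_learning_rate = initial_learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), task_type = task_type,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- early stopping state machine (pure, testable in isolation) ----

early_stopping_init <- function(patience) {
  list(patience = as.integer(patience), best_loss = Inf, best_epoch = 0L,
       wait = 0L, stop = FALSE, epoch = 0L)
}

# strict decrease counts as improvement; ties do not
early_stopping_update <- function(es, loss) {
  es$epoch <- es$epoch + 1L
  if (loss < es$best_loss) {
    es$best_loss <- loss
    es$best_epoch <- es$epoch
    es$wait <- 0L
  } else {
    es$wait <- es$wait + 1L
    if (es$wait >= es$patience) es$stop <- TRUE
  }
  es
}

# run the controller over a precomputed loss trajectory (used by tests and
# by anyone auditing the stopping rule)
early_stopping_trace <- function(losses, patience) {
  es <- early_stopping_init(patience)
  for (l in losses) {
    es <- early_stopping_update(es, l)
    if (es$stop) break
  }
  list(best_epoch = es$best_epoch, stopped_epoch = es$epoch,
       best_loss = es$best_loss)
}

# ---- Adam optimizer over a parameter tree ----

adam_init <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v)
    p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

#' Train a GNN/CGNN model
#'
#' Full-batch Adam with validation-based early stopping: after every epoch
#' the validation loss is evaluated; when it fails to strictly improve for
#' `patience` consecutive epochs, training stops and the weights of the
#' best-validation epoch are restored. Regression targets are min-max
#' normalized on the training split before the loss is computed.
#'
#' @param model A [gnn_model()] or [cgnn_model()].
#' @param train,valid Graph lists or [batch_graphs()] batches sharing task
#'   structure.
#' @param cfg A [train_config()].
#' @return An object of class `gnn_fit`: the trained `model`, a per-epoch
#'   `record` tibble, `best_epoch`, `stopped_epoch`, `restored`, and the
#'   `normalizer` (regression only).
#' @export
fit_gnn <- function(model, train, valid, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  train <- as_graph_batch(train)
  valid <- as_graph_batch(valid)
  if (train$n_tasks != valid$n_tasks) {
    stop("train and validation splits disagree on task count", call. = FALSE)
  }
  if (train$n_tasks != model$n_tasks) {
    stop("model has ", model$n_tasks, " task(s) but data has ",
         train$n_tasks, call. = FALSE)
  }
  normalizer <- NULL
  y_train <- train$targets
  y_valid <- valid$targets
  if (cfg$task_type == "regression") {
    normalizer <- normalize_targets(y_train)
    y_train <- normalize_apply(normalizer, y_train)
    y_valid <- normalize_apply(normalizer, y_valid)
  }
  opt <- adam_init(model$params)
  es <- early_stopping_init(cfg$patience)
  best_params <- model$params
  record <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    fwd <- forward_model(model, train)
    train_loss <- masked_loss(fwd$Y, y_train, cfg$task_type)
    if (!is.finite(train_loss)) {
      stop("non-finite training loss at epoch ", epoch,
           " (learning rate ", cfg$initial_learning_rate, ")", call. = FALSE)
    }
    d_Y <- masked_loss_grad(fwd$Y, y_train, cfg$task_type)
    grads <- backward_model(model, train, fwd, d_Y)
    upd <- adam_step(model$params, grads, opt, cfg$initial_learning_rate)
    model$params <- upd$params
    opt <- upd$state
    valid_fwd <- forward_model(model, valid)
    valid_loss <- masked_loss(valid_fwd$Y, y_valid, cfg$task_type)
    if (!is.finite(valid_loss)) {
      stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
    }
    record[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                         valid_loss = valid_loss)
    improved_to <- valid_loss < es$best_loss
    es <- early_stopping_update(es, valid_loss)
    if (improved_to) best_params <- model$params
    if (es$stop) break
  }
  stopped_epoch <- es$epoch
  restored <- es$best_epoch < stopped_epoch
  model$params <- best_params
  structure(
    list(model = model,
         record = tibble::as_tibble(do.call(rbind, record[seq_len(stopped_epoch)])),
         best_epoch = es$best_epoch, stopped_epoch = stopped_epoch,
         best_valid_loss = es$best_loss, restored = restored,
         normalizer = normalizer, config = cfg),
    class = "gnn_fit"
  )
}

#' @export
print.gnn_fit <- function(x, ...) {
  cat(sprintf(
    "<gnn_fit> %s: stopped at epoch %d (best epoch %d, valid loss %.4g%s)\n",
    x$model$kind, x$stopped_epoch, x$best_epoch, x$best_valid_loss,
    if (x$restored) ", best weights restored" else ""))
  invisible(x)
}

#' Predictions of a fitted model on the original target scale
#'
#' @param object A [fit_gnn()] result.
#' @param graphs Graphs or a batch.
#' @param ... Unused.
#' @return A tibble as in [predict.gnn_model()]; regression predictions are
#'   mapped back to the raw target scale through the stored normalizer.
#' @export
predict.gnn_fit <- function(object, graphs, ...) {
  out <- predict(object$model, graphs)
  if (!is.null(object$normalizer)) {
    cols <- paste0("task", seq_len(object$model$n_tasks))
    out[cols] <- normalize_invert(object$normalizer,
                                  as.matrix(out[cols]))
  }
  out
}
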