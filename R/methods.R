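#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch training record of a fit
#'
#' @param x A [fit_gnn()] result.
#' @param ... Unused.
#' @return A long tibble with `epoch`, `split` (train/valid) and `loss`.
#' @method tidy gnn_fit
#' @export
tidy.gnn_fit <- function(x, ...) {
  if (is.null(x$record)) {
    return(tibble::tibble(epoch = integer(), split = character(),
                          loss = numeric()))
  }
  tidyr::pivot_longer(x$record, cols = c("train_loss", "valid_loss"),
                      names_to = "split", values_to = "loss",
                      names_pattern = "(.*)_loss")
}

#' One-row summary of a fit
#'
#' @param x A [fit_gnn()] result.
#' @param ... Unused.
#' @method glance gnn_fit
#' @export
glance.gnn_fit <- function(x, ...) {
  tibble::tibble(
    model_kind = x$model$kind,
    task_type = x$config$task_type,
    learning_rate = x$config$initial_learning_rate,
    epochs_run = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_valid_loss = x$best_valid_loss,
    restored = x$restored
  )
}

#' Training-curve plot
#'
#' Train and validation loss per epoch, with the restored best epoch marked.
#'
#' @param object A [fit_gnn()] result.
#' @param ... Unused.
#' @method autoplot gnn_fit
#' @export
autoplot.gnn_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = sprintf("%s training (best epoch %d)",
                                  object$model$kind, object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Tidy per-configuration sweep results
#'
#' @param x A [run_sweep()] result.
#' @param ... Unused.
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) x$results

#' One-row summary of a sweep
#'
#' @param x A [run_sweep()] result.
#' @param ... Unused.
#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, direction = x$direction,
    n_configs = nrow(x$results),
    n_failed = sum(x$results$status == "failed"),
    best_config_id = x$best_config_id,
    best_model_kind = x$best_model_kind,
    best_valid_value = x$best_valid_value,
    test_value = x$test_value
  )
}

#' Validation-metric profile of a sweep
#'
#' @param object A [run_sweep()] result.
#' @param ... Unused.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  d <- dplyr::filter(object$results, .data$status == "ok")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$config_id,
                                  y = .data$valid_value,
                                  colour = .data$af,
                                  shape = .data$model_kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$best_valid_value,
                        linetype = 2) +
    ggplot2::labs(x = "configuration", y = paste("validation", object$metric),
                  colour = "activation", shape = "model") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
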