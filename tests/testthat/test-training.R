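test_that("masked binary cross-entropy has its closed forms", {
  # all labels observed: equals plain mean BCE
  p <- matrix(c(0.9, 0.2, 0.7, 0.4), 2L)
  y <- matrix(c(1, 0, 1, 0), 2L)
  expect_equal(masked_loss(p, y, "binary"),
               -mean(y * log(p) + (1 - y) * log(1 - p)))
  # prediction 0.5 on every observed label -> ln 2
  expect_equal(masked_loss(matrix(0.5, 3L, 2L),
                           matrix(c(1, 0, NA, 1, 0, NA), 3L), "binary"),
               log(2))
  expect_error(masked_loss(matrix(0.5, 2L, 1L), matrix(NA_real_, 2L, 1L),
                           "binary"), "missing")
  expect_error(masked_loss(matrix(0.5, 2L, 1L), matrix(0, 1L, 1L)),
               "shapes")
})

test_that("masked losses match an explicit-loop oracle on masked entries", {
  withr::with_seed(33L, {
    p <- matrix(runif(24L, 0.05, 0.95), 6L, 4L)
    y <- matrix(rbinom(24L, 1L, 0.5), 6L, 4L)
    y[sample(24L, 12L)] <- NA # half the entries missing
  })
  acc <- 0; k <- 0L
  for (i in 1:6) for (j in 1:4) {
    if (!is.na(y[i, j])) {
      acc <- acc - (y[i, j] * log(p[i, j]) + (1 - y[i, j]) * log(1 - p[i, j]))
      k <- k + 1L
    }
  }
  expect_equal(masked_loss(p, y, "binary"), acc / k)
  acc2 <- 0
  for (i in 1:6) for (j in 1:4) {
    if (!is.na(y[i, j])) acc2 <- acc2 + (p[i, j] - y[i, j])^2
  }
  expect_equal(masked_loss(p, y, "regression"), acc2 / k)
})

test_that("target normalization is an invertible affine map onto [0, 1]", {
  norm <- normalize_targets(matrix(c(-4, 0, 4), 3L))
  expect_equal(as.numeric(normalize_apply(norm, matrix(c(-4, 0, 4), 3L))),
               c(0, 0.5, 1))
  y <- matrix(withr::with_seed(5L, rnorm(20L, 2, 3)), 10L, 2L)
  norm2 <- normalize_targets(y)
  expect_equal(normalize_invert(norm2, normalize_apply(norm2, y)), y)
  expect_error(normalize_targets(matrix(1, 5L, 1L)), "distinct")
})

test_that("analytic gradients match central finite differences", {
  # 5-graph fixture, both model kinds, binary and regression heads
  cases <- list(list(kind = "gnn", task = "binary"),
                list(kind = "cgnn", task = "binary"),
                list(kind = "cgnn", task = "regression"))
  ds <- generate_graphs(fixture_spec(n_graphs = 5L,
                                     node_count_range = c(2L, 5L),
                                     task = "regression", seed = 11L))
  gs_raw <- c(ds$train, ds$valid, ds$test)
  for (case in cases) {
    gs <- if (case$kind == "gnn") lapply(gs_raw, homogenize)
      else lapply(gs_raw, heterogenize)
    b <- batch_graphs(gs)
    m <- if (case$kind == "gnn") {
      gnn_model(2L, 1L, node_feature_dim = 8L, hidden_state = 4L,
                hidden_output = 3L, activation = "tanh", K = 3L,
                init_scale = 0.05, seed = 5L)
    } else {
      cgnn_model(2L, 1L, hidden_state = 4L, hidden_output = 3L,
                 activation = "tanh", K = 3L, init_scale = 0.05, seed = 5L)
    }
    y <- b$targets
    if (case$task == "binary") {
      y <- matrix(as.numeric(y > median(y)), ncol = 1L)
    } else {
      y <- normalize_apply(normalize_targets(y), y)
    }
    fwd <- compgnn:::forward_model(m, b)
    grads <- compgnn:::backward_model(
      m, b, fwd, compgnn:::masked_loss_grad(fwd$Y, y, case$task))
    skeleton <- m$params
    loss_at <- function(v) {
      m2 <- m
      m2$params <- utils::relist(v, skeleton)
      masked_loss(compgnn:::forward_model(m2, b)$Y, y, case$task)
    }
    v0 <- unlist(skeleton)
    analytic <- unlist(grads)
    numeric_g <- vapply(seq_along(v0), function(i) {
      e <- v0; e[i] <- v0[i] + 1e-5; lp <- loss_at(e)
      e[i] <- v0[i] - 1e-5; lm <- loss_at(e)
      (lp - lm) / 2e-5
    }, numeric(1))
    rel <- abs(analytic - numeric_g) / pmax(abs(analytic) + abs(numeric_g), 1)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("the early-stopping controller follows the patience rule", {
  # worsening from epoch 1 for 10 epochs: stop at epoch 11, keep epoch 1
  tr <- compgnn:::early_stopping_trace(c(1, 1 + (1:10) / 10), patience = 10L)
  expect_identical(tr$stopped_epoch, 11L)
  expect_identical(tr$best_epoch, 1L)
  # strictly improving: never stops, best is the last epoch
  tr2 <- compgnn:::early_stopping_trace(seq(1, 0.1, length.out = 30L),
                                        patience = 10L)
  expect_identical(tr2$stopped_epoch, 30L)
  expect_identical(tr2$best_epoch, 30L)
  # ties count as non-improvement
  tr3 <- compgnn:::early_stopping_trace(c(0.5, rep(0.5, 10L)),
                                        patience = 10L)
  expect_identical(tr3$stopped_epoch, 11L)
  expect_identical(tr3$best_epoch, 1L)
  # a late improvement resets the counter
  tr4 <- compgnn:::early_stopping_trace(c(1, 1.1, 1.2, 0.9, rep(1, 10L)),
                                        patience = 10L)
  expect_identical(tr4$stopped_epoch, 14L)
  expect_identical(tr4$best_epoch, 4L)
})

test_that("training restores the best-validation weights", {
  ds <- generate_graphs(fixture_spec(n_graphs = 40L,
                                     node_count_range = c(3L, 8L),
                                     task = "binary", noise_level = 0.2,
                                     seed = 7L))
  train <- lapply(ds$train, heterogenize)
  valid <- lapply(ds$valid, heterogenize)
  m <- cgnn_model(3L, 1L, hidden_state = 5L, hidden_output = 5L, K = 3L,
                  seed = 3L)
  fit <- fit_gnn(m, train, valid,
                 train_config(5e-2, max_epochs = 40L, patience = 5L,
                              task_type = "binary", seed = 3L))
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  expect_equal(fit$best_valid_loss, min(fit$record$valid_loss))
  # restored weights really reproduce the best epoch's validation loss
  vb <- batch_graphs(valid)
  y <- graph_output(vb, propagate(vb, fit$model), fit$model)
  expect_equal(masked_loss(y, vb$targets, "binary"), fit$best_valid_loss,
               tolerance = 1e-10)
})

test_that("training is reproducible from (data, config, seed)", {
  ds <- generate_graphs(fixture_spec(n_graphs = 24L,
                                     node_count_range = c(3L, 6L),
                                     task = "binary", seed = 13L))
  train <- lapply(ds$train, homogenize)
  valid <- lapply(ds$valid, homogenize)
  run <- function() {
    m <- gnn_model(2L, 1L, node_feature_dim = 8L, hidden_state = 4L,
                   K = 2L, seed = 8L)
    fit_gnn(m, train, valid,
            train_config(1e-2, max_epochs = 15L, patience = 10L,
                         task_type = "binary", seed = 8L))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$record, f2$record)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a trivially separable fixture is overfit below 0.05 loss", {
  gs <- separable_fixture()
  train <- lapply(gs, heterogenize)
  m <- cgnn_model(3L, 1L, hidden_state = 10L, hidden_output = 10L, K = 2L,
                  activation = "tanh", seed = 1L)
  fit <- fit_gnn(m, train, train,
                 train_config(1e-2, max_epochs = 300L, patience = 300L,
                              task_type = "binary", seed = 1L))
  expect_lt(min(fit$record$train_loss), 0.05)
})
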