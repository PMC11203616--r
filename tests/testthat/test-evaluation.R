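test_that("AUROC hits its trivial anchors", {
  labels <- c(0, 1, 0, 1, 1, 0)
  expect_equal(auroc(labels, labels), 1)
  expect_equal(auroc(1 - labels, labels), 0)
  # mid-rank tie handling: all scores equal -> 0.5
  expect_equal(auroc(rep(0.3, 6L), labels), 0.5)
  expect_error(auroc(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("AUROC equals exhaustive concordant-pair counting", {
  score_sets <- list(
    list(s = c(0.1, 0.4, 0.35, 0.8), y = c(0, 0, 1, 1)),
    list(s = withr::with_seed(2L, runif(40L)),
         y = withr::with_seed(3L, rbinom(40L, 1L, 0.4))),
    list(s = withr::with_seed(4L, sample(1:10, 40L, TRUE)), # many ties
         y = withr::with_seed(5L, rbinom(40L, 1L, 0.5)))
  )
  for (case in score_sets) {
    pos <- which(case$y == 1); neg <- which(case$y == 0)
    acc <- 0
    for (i in pos) for (j in neg) {
      acc <- acc + (case$s[i] > case$s[j]) + 0.5 * (case$s[i] == case$s[j])
    }
    expect_equal(auroc(case$s, case$y), acc / (length(pos) * length(neg)))
  }
})

test_that("AUROC is invariant under monotone transforms and flips under negation", {
  s <- withr::with_seed(8L, runif(60L))
  y <- withr::with_seed(9L, rbinom(60L, 1L, 0.5))
  a <- auroc(s, y)
  expect_equal(auroc(exp(3 * s) + 1, y), a)
  expect_equal(auroc(rank(s), y), a)
  expect_equal(auroc(-s, y) + a, 1) # tie-free complement identity
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  s <- withr::with_seed(10L, runif(200L))
  y <- withr::with_seed(11L, rbinom(200L, 1L, 0.35))
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("multi-task AUROC averages valid tasks and drops single-class ones", {
  s <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.6, 0.5, 0.4, 0.3))
  y <- cbind(c(1, 1, 0, 0), c(1, 1, 1, 1)) # task 2 has one class
  expect_warning(res <- auroc_multitask(s, y), "dropped")
  expect_equal(res$value, 1)
  expect_true(is.na(res$per_task[2L]))
  # missing labels are excluded per task
  y2 <- cbind(c(1, NA, 0, 0), c(0, 1, NA, 1))
  res2 <- auroc_multitask(s, y2)
  expect_equal(res2$per_task[1L], auroc(s[c(1, 3, 4), 1L], c(1, 0, 0)))
  expect_error(auroc_multitask(s, cbind(c(1, 1, 1, 1), c(0, 0, 0, 0))),
               "no task")
})

test_that("average precision matches a hand-enumerated ranking oracle", {
  # perfect ranking in every task -> 1
  s <- cbind(c(0.9, 0.7, 0.2), c(0.8, 0.6, 0.1))
  y <- cbind(c(1, 1, 0), c(1, 0, 0))
  expect_equal(average_precision(s, y)$value, 1)
  expect_equal(average_precision(matrix(c(0.9, 0.1), 2L),
                                 matrix(c(1, 0), 2L))$value, 1)
  # 5 items, mixed ranks: sorted labels (1, 0, 1, 0, 1) ->
  # precision at the positives: 1/1, 2/3, 3/5
  s5 <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.5), 5L)
  y5 <- matrix(c(1, 0, 1, 0, 1), 5L)
  expect_equal(average_precision(s5, y5)$value, mean(c(1, 2 / 3, 3 / 5)))
  expect_error(average_precision(s5, matrix(0, 5L)), "no positives")
})

test_that("RMSE matches its arithmetic definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 2), c(1, 3)), 1)
  p <- withr::with_seed(12L, rnorm(50L))
  t <- withr::with_seed(13L, rnorm(50L))
  acc <- 0
  for (i in seq_along(p)) acc <- acc + (p[i] - t[i])^2
  expect_equal(rmse(p, t), sqrt(acc / 50))
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("datasets dispatch to their benchmark metric", {
  expect_identical(metric_for_dataset("FreeSolv"), "rmse")
  expect_identical(metric_for_dataset("MUV"), "ap")
  for (d in c("HIV", "Tox-21", "BACE", "BBBP", "ClinTox", "Sider")) {
    expect_identical(metric_for_dataset(d), "auroc")
  }
  expect_identical(metric_for_dataset("ogbg-molhiv"), "auroc")
  expect_error(metric_for_dataset("unknown"), "unknown dataset")
  expect_identical(metric_direction("rmse"), "minimize")
  expect_identical(metric_direction("auroc"), "maximize")
})

test_that("evaluate_model guards task structure and reports a tidy record", {
  ds <- generate_graphs(fixture_spec(n_graphs = 30L,
                                     node_count_range = c(3L, 6L),
                                     task = "binary", seed = 19L))
  train <- lapply(ds$train, heterogenize)
  m <- cgnn_model(2L, 1L, hidden_state = 4L, K = 2L, seed = 2L)
  fit <- fit_gnn(m, train, lapply(ds$valid, heterogenize),
                 train_config(1e-2, max_epochs = 5L, patience = 10L,
                              task_type = "binary", seed = 2L))
  rep <- evaluate_model(fit, lapply(ds$test, heterogenize), "auroc")
  expect_s3_class(rep, "tbl_df")
  expect_true(rep$value >= 0 && rep$value <= 1)
  expect_identical(rep$n_examples, 3L)
  expect_error(evaluate_model(fit, lapply(ds$test, heterogenize), "rmse"),
               "does not match")
})
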