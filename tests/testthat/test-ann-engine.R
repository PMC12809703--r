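test_that("a one-neuron network recovers a linear single-descriptor signal", {
  toy <- linear_toy()
  xs <- autoscale(toy$x)
  ts <- autoscale(toy$t)
  split <- toy_split(nrow(toy$x))
  model <- train_ann(xs$x[, "a", drop = FALSE], ts$x, split,
                     ann_topology(1, 0),
                     training_config(max_epochs = 2000, patience = 200,
                                     seed = 3))
  y <- eesprofiler:::forward_ann(model$weights, model$topology,
                                 xs$x[, "a", drop = FALSE])
  r2 <- cor(as.vector(y[split$tr, ]), as.vector(ts$x[split$tr, ]))^2
  expect_gte(r2, 0.99)
})

test_that("constant targets are reproduced on every subset", {
  # constant target columns autoscale to zeros with recorded scale 0, and
  # descaling restores the constant regardless of what the network emits
  ds <- default_dataset()
  t_const <- unclass(ds$target)
  t_const[] <- rep(c(1.5, -1, 0), each = nrow(t_const) * 3)
  class(t_const) <- c("target_matrix", class(t_const))
  set.seed(5)
  vec <- runif(74)
  ev <- evaluate_candidate(vec, ds$descriptors, t_const,
                           training_config(max_epochs = 50))
  y <- predict_ann(ev$model, ds$descriptors, clip = FALSE)
  expect_lt(max(abs(sweep(unclass(y), 2, t_const[1, ], "-"))), 1e-6)
})

test_that("training is bit-for-bit reproducible under a fixed seed", {
  toy <- linear_toy()
  xs <- autoscale(toy$x); ts <- autoscale(toy$t)
  split <- toy_split(nrow(toy$x))
  cfg <- training_config(max_epochs = 300, seed = 17)
  m1 <- train_ann(xs$x, ts$x, split, ann_topology(5, 3), cfg)
  m2 <- train_ann(xs$x, ts$x, split, ann_topology(5, 3), cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$diagnostics$va_mse, m2$diagnostics$va_mse)
})

test_that("early stopping reports the minimum validation error seen", {
  toy <- linear_toy()
  xs <- autoscale(toy$x); ts <- autoscale(toy$t)
  split <- toy_split(nrow(toy$x))
  m <- train_ann(xs$x, ts$x, split, ann_topology(8, 0),
                 training_config(max_epochs = 400, patience = 15, seed = 1))
  expect_equal(m$diagnostics$va_mse, min(m$diagnostics$va_history))
  expect_lte(m$diagnostics$best_epoch, m$diagnostics$epochs_run)
})

test_that("topology with n2 = 0 has a single hidden layer", {
  toy <- linear_toy()
  xs <- autoscale(toy$x); ts <- autoscale(toy$t)
  split <- toy_split(nrow(toy$x))
  m <- train_ann(xs$x, ts$x, split, ann_topology(6, 0),
                 training_config(max_epochs = 50, seed = 1))
  expect_equal(dim(m$weights$W2), c(0, 0))
  expect_equal(dim(m$weights$W1), c(3, 6))
  expect_equal(dim(m$weights$W3), c(6, 9))
})

test_that("prediction output shape and determinism hold, clipping optional", {
  ds <- default_dataset()
  set.seed(21)
  vec <- runif(74); vec[13:17] <- 0.9
  ev <- evaluate_candidate(vec, ds$descriptors, ds$target,
                           training_config(max_epochs = 150))
  one <- predict_ann(ev$model, unclass(ds$descriptors)[1, , drop = FALSE])
  expect_equal(dim(one), c(1, 9))
  p1 <- predict_ann(ev$model, ds$descriptors)
  p2 <- predict_ann(ev$model, ds$descriptors)
  expect_identical(p1, p2)
  expect_true(all(p1 >= -1 & p1 <= 6))
  raw <- predict_ann(ev$model, ds$descriptors, clip = FALSE)
  expect_true(any(raw < -1 | raw > 6) || identical(raw, unclass(p1)))
})

test_that("prediction on a training row reproduces the values the metrics saw", {
  ds <- default_dataset()
  set.seed(8)
  vec <- runif(74)
  ev <- evaluate_candidate(vec, ds$descriptors, ds$target,
                           training_config(max_epochs = 150))
  # recompute the objective-path predictions independently
  xsc <- autoscale(unclass(ds$descriptors))
  y_obj <- descale(
    eesprofiler:::forward_ann(ev$model$weights, ev$model$topology,
                              xsc$x[, ev$model$feature_mask, drop = FALSE]),
    ev$model$t_scaler)
  y_pred <- predict_ann(ev$model, ds$descriptors, clip = FALSE)
  expect_identical(unname(y_obj), unname(unclass(y_pred)))
})

test_that("prediction demands the full descriptor schema", {
  ds <- default_dataset()
  set.seed(9)
  vec <- runif(74)
  ev <- evaluate_candidate(vec, ds$descriptors, ds$target,
                           training_config(max_epochs = 60))
  x_missing <- unclass(ds$descriptors)[, -5]
  expect_error(predict_ann(ev$model, x_missing), "missing descriptor")
})

test_that("invalid topologies and degenerate splits are rejected", {
  expect_error(ann_topology(0, 0), "n1")
  expect_error(ann_topology(31, 0), "n1")
  expect_error(ann_topology(5, 31), "n2")
  toy <- linear_toy()
  xs <- autoscale(toy$x); ts <- autoscale(toy$t)
  bad <- subset_split(1, 2:39, integer(0))
  expect_error(train_ann(xs$x, ts$x, bad, ann_topology(2, 0)), "degenerate")
})
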