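test_that("a separable toy task is learned to perfect validation accuracy with early stop", {
  toy <- toy_images(20, seed = 1)
  val <- toy_images(8, seed = 2)
  # min_delta large enough that the slow tail of loss decay counts as plateau
  cfg <- train_config(max_epochs = 60, early_stop_patience = 6, lr_reduce_patience = 3,
                      min_delta = 0.05, seed = 4,
                      backbone_args = list(input_size = 8, hidden = 8))
  res <- train_supervised(toy$images, toy$labels, val$images, val$labels, config = cfg)
  h <- res$history
  expect_equal(max(h$epochs$val_acc), 1.0)
  expect_true(h$stopped_early)
  expect_lt(nrow(h$epochs), 60)
  # checkpoint invariants
  expect_equal(h$best_epoch, which.min(h$epochs$val_loss))
  expect_true(all(diff(h$epochs$lr) <= 0))
})

test_that("learning-rate reduction fires on a plateau before stopping", {
  toy <- toy_images(5, seed = 3)
  val <- toy_images(3, seed = 4)
  # min_delta so large that no epoch ever counts as improvement
  cfg <- train_config(max_epochs = 10, lr_reduce_patience = 1, early_stop_patience = 3,
                      min_delta = 10, seed = 1,
                      backbone_args = list(input_size = 8, hidden = 4))
  res <- train_supervised(toy$images, toy$labels, val$images, val$labels, config = cfg)
  lrs <- unique(res$history$epochs$lr)
  expect_true(all(c(0.001, 0.0001) %in% lrs))
  expect_true(res$history$stopped_early)
})

test_that("the returned model is the best checkpoint, not the last epoch", {
  toy <- toy_images(10, seed = 5)
  val <- toy_images(5, seed = 6)
  cfg <- fast_train_config(seed = 2, backbone_args = list(input_size = 8, hidden = 8))
  res <- train_supervised(toy$images, toy$labels, val$images, val$labels, config = cfg)
  P <- predict_proba(res$model, val$images)
  y <- as.integer(val$labels)
  model_val_loss <- -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))
  last_val_loss <- utils::tail(res$history$epochs$val_loss, 1)
  expect_lte(model_val_loss, last_val_loss + 1e-9)
  expect_equal(model_val_loss, res$history$epochs$val_loss[res$history$best_epoch],
               tolerance = 1e-9)
})

test_that("single-class labeled sets are rejected naming the missing classes", {
  toy <- toy_images(4, seed = 7)
  keep <- toy$labels == "normal"
  expect_error(
    train_supervised(toy$images[keep], toy$labels[keep], toy$images, toy$labels,
                     config = fast_train_config()),
    "drusen, cnv")
})

test_that("predict_proba satisfies the softmax contract and inference determinism", {
  toy <- toy_images(8, seed = 8)
  val <- toy_images(4, seed = 9)
  cfg <- fast_train_config(seed = 3, backbone_args = list(input_size = 8, hidden = 8))
  model <- train_supervised(toy$images, toy$labels, val$images, val$labels, config = cfg)$model
  batch <- c(val$images[1], val$images[1], val$images[2])
  P <- predict_proba(model, batch)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0))
  expect_identical(P[1, ], P[2, ])
  expect_error(predict_proba(clone_untrained(model), batch), "untrained")
})

test_that("training is reproducible under a fixed seed and scale-invariant in weights", {
  toy <- toy_images(8, seed = 10)
  val <- toy_images(4, seed = 11)
  cfg <- fast_train_config(seed = 5, backbone_args = list(input_size = 8, hidden = 8))
  r1 <- train_supervised(toy$images, toy$labels, val$images, val$labels, config = cfg)
  r2 <- train_supervised(toy$images, toy$labels, val$images, val$labels, config = cfg)
  expect_identical(r1$history$epochs, r2$history$epochs)
  # doubling every sample weight cannot change the normalized loss or its argmin
  w <- class_weights(toy$labels)
  r3 <- train_supervised(toy$images, toy$labels, val$images, val$labels,
                         weights = 2 * w, config = cfg)
  expect_equal(r1$history$epochs, r3$history$epochs, tolerance = 1e-9)
  cfg2 <- fast_train_config(seed = 6, backbone_args = list(input_size = 8, hidden = 8))
  r4 <- train_supervised(toy$images, toy$labels, val$images, val$labels, config = cfg2)
  expect_false(identical(r1$history$epochs, r4$history$epochs))
})

test_that("the backbone registry exposes pluggable architectures", {
  expect_true(all(c("small_mlp", "softmax_linear") %in% registered_backbones()))
  expect_error(new_backbone("efficientnet_b0"), "unknown backbone")
  clf <- new_backbone("softmax_linear", input_size = 8)
  expect_false(is_trained(clf))
  toy <- toy_images(15, seed = 12)
  val <- toy_images(5, seed = 13)
  cfg <- fast_train_config(seed = 1, max_epochs = 30L, backbone = "softmax_linear",
                           backbone_args = list(input_size = 8),
                           batch_size = 16L, learning_rate = 0.01)
  res <- train_supervised(toy$images, toy$labels, val$images, val$labels, config = cfg)
  expect_gte(max(res$history$epochs$val_acc), 0.9)
})

test_that("train_config enforces the patience ordering", {
  expect_error(train_config(lr_reduce_patience = 15, early_stop_patience = 10),
               "lr_reduce_patience")
})
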