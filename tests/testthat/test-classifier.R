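test_that("model construction fixes the interface and the parameter count", {
  m2 <- build_cnn(cnn_config(input_shape = c(16, 16, 3)), 2)
  m4 <- build_cnn(cnn_config(input_shape = c(16, 16, 3)), 4)
  expect_equal(m2$n_classes, 2)
  expect_equal(m4$n_classes, 4)
  expect_error(build_cnn(cnn_config(input_shape = c(16, 16, 3)), 3), "n_classes")
  expect_error(cnn_config(input_shape = c(20, 20, 3)), "divisible")
  # parameter count: conv 3x3 blocks + dense head, identical across builds
  expect_equal(cnn_num_params(m2), cnn_num_params(build_cnn(cnn_config(
    input_shape = c(16, 16, 3)), 2)))
  expect_equal(cnn_num_params(m2),
               (9 * 3 * 8 + 8) + (9 * 8 * 16 + 16) + (9 * 16 * 32 + 32) +
                 (2 * 2 * 32) * 2 + 2)
  # canonical 224x224x3 architecture builds with the default filter counts
  full <- build_cnn(cnn_config(), 4)
  expect_equal(full$flat_dim, 28 * 28 * 32)
})

test_that("training fits strongly separable scalogram-like images", {
  toy <- toy_images(20, size = 16, seed = 1)
  model <- build_cnn(cnn_config(input_shape = c(16, 16, 3)), 2)
  fit <- train_cnn(model, toy,
                   config = train_config(epochs = 20, batch_size = 32,
                                         rng_seed = 1))
  expect_equal(nrow(fit$history), 20)
  expect_gte(fit$history$accuracy[20], 0.9)
  # prediction contracts
  p <- predict(fit, toy$x)
  expect_true(all(abs(rowSums(p$probs) - 1) < 1e-6))
  expect_true(all(p$labels %in% c("A", "B")))
  p0 <- predict(fit, toy$x[, , , 0, drop = FALSE])
  expect_equal(nrow(p0$probs), 0)
  expect_length(p0$labels, 0)
  p_again <- predict(fit, toy$x)
  expect_identical(p$probs, p_again$probs)
  expect_error(predict(fit, array(0, dim = c(8, 8, 3, 2))), "shape")
  # single-class training set rejected
  one <- list(x = toy$x[, , , 1:20, drop = FALSE], y = rep("A", 20))
  expect_error(train_cnn(model, one), "single class")
})

test_that("identical seed and data reproduce training exactly", {
  toy <- toy_images(10, size = 16, seed = 2)
  model <- build_cnn(cnn_config(input_shape = c(16, 16, 3)), 2)
  cfg <- train_config(epochs = 5, batch_size = 8, rng_seed = 42)
  f1 <- train_cnn(model, toy, config = cfg)
  f2 <- train_cnn(model, toy, config = cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$weights$dense$W, f2$weights$dense$W)
})

test_that("randomly permuted labels give chance-level validation accuracy", {
  # unstructured noise images carry nothing learnable, so a model trained on
  # permuted labels must sit at chance on held-out data
  noise_set <- function(n, seed) {
    set.seed(seed)
    list(x = array(runif(16 * 16 * 3 * n), dim = c(16, 16, 3, n)),
         y = rep(c("A", "B"), each = n / 2))
  }
  trn <- noise_set(32, seed = 30)
  val <- noise_set(20, seed = 31)
  accs <- sapply(1:5, function(s) {
    set.seed(1000 + s)
    shuffled <- list(x = trn$x, y = sample(trn$y))
    model <- build_cnn(cnn_config(input_shape = c(16, 16, 3)), 2)
    fit <- train_cnn(model, shuffled, val,
                     config = train_config(epochs = 6, batch_size = 8,
                                           rng_seed = s))
    fit$history$val_accuracy[6]
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("the optimizer sweep trains all three optimizers under one config", {
  toy <- toy_images(10, size = 16, seed = 5)
  model <- build_cnn(cnn_config(input_shape = c(16, 16, 3)), 2)
  sweep <- optimizer_sweep(model, toy,
                           config = train_config(epochs = 4, batch_size = 8,
                                                 rng_seed = 1))
  expect_equal(sweep$optimizer, c("rmsprop", "sgdm", "adam"))
  expect_true(all(c("loss", "accuracy") %in% names(sweep)))
  expect_length(attr(sweep, "models"), 3)
  # every optimizer actually reduced the loss from its first epoch
  for (m in attr(sweep, "models")) {
    expect_lt(m$history$loss[4], m$history$loss[1])
  }
})
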