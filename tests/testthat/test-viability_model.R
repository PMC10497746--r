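tiny_cfg <- function(arch = "multiscale", K = 6L, ...) {
  model_config(arch, input_shape = c(5L, 5L, K),
               filters_per_module = c(2L, 3L, 2L), fc_width = 8L, ...)
}

test_that("forward pass yields softmax rows and the documented widths", {
  cfg <- model_config("multiscale", input_shape = c(5L, 5L, 18L), seed = 2)
  m <- build_model(cfg)
  expect_equal(m$module_channels, c(64L, 128L, 256L))  # 4 branches x filters
  bs <- make_separable_blocks(n_per_class = 3, K = 18, seed = 1)
  pr <- predict_blocks(m, bs)
  expect_equal(dim(pr$scores), c(6L, 2L))
  expect_equal(rowSums(pr$scores), rep(1, 6), tolerance = 1e-6)
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
})

test_that("conventional and multiscale builders accept identical inputs", {
  bs <- make_separable_blocks(n_per_class = 2, K = 6, seed = 2)
  for (arch in c("multiscale", "conventional")) {
    m <- build_model(tiny_cfg(arch, seed = 3))
    pr <- predict_blocks(m, bs)
    expect_equal(dim(pr$scores), c(4L, 2L))
  }
  mc <- build_model(model_config("conventional", input_shape = c(5, 5, 6),
                                 seed = 1))
  expect_equal(mc$module_channels, c(16L, 32L, 64L))  # single branch
})

test_that("zeroed output layer gives symmetric 0.5 scores", {
  m <- build_model(tiny_cfg(seed = 4))
  m$weights$fc2_W[] <- 0
  m$weights$fc2_b[] <- 0
  bs <- make_separable_blocks(n_per_class = 2, K = 6, seed = 3)
  pr <- predict_blocks(m, bs)
  expect_equal(pr$scores, matrix(0.5, 4, 2), ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg(seed = 5)
  m <- build_model(cfg)
  set.seed(6)
  x <- rnorm(6 * 25 * 4)
  y <- c(1L, 2L, 2L, 1L)
  kern <- do.call(rbind, cfg$kernel_bank)
  args <- list(kern, cfg$filters_per_module, as.integer(cfg$pool_after),
               c(6L, 5L, 5L), cfg$fc_width, 2L)
  lg <- do.call(seedhsi:::cnn3d_loss_grad, c(list(m$weights), args,
                                             list(x, y)))
  eps <- 1e-3
  for (li in c(1L, 6L, 11L)) {
    g <- lg$grad$conv_W[[li]]
    idx <- which.max(abs(g))
    wp <- m$weights; wm <- m$weights
    wp$conv_W[[li]][idx] <- wp$conv_W[[li]][idx] + eps
    wm$conv_W[[li]][idx] <- wm$conv_W[[li]][idx] - eps
    fp <- do.call(seedhsi:::cnn3d_loss_grad, c(list(wp), args, list(x, y)))$loss
    fm <- do.call(seedhsi:::cnn3d_loss_grad, c(list(wm), args, list(x, y)))$loss
    expect_equal(g[idx], (fp - fm) / (2 * eps), tolerance = 5e-3)
  }
  for (nm in c("fc1_W", "fc2_W")) {
    g <- lg$grad[[nm]]
    idx <- which.max(abs(g))
    wp <- m$weights; wm <- m$weights
    wp[[nm]][idx] <- wp[[nm]][idx] + eps
    wm[[nm]][idx] <- wm[[nm]][idx] - eps
    fp <- do.call(seedhsi:::cnn3d_loss_grad, c(list(wp), args, list(x, y)))$loss
    fm <- do.call(seedhsi:::cnn3d_loss_grad, c(list(wm), args, list(x, y)))$loss
    expect_equal(g[idx], (fp - fm) / (2 * eps), tolerance = 5e-3)
  }
})

test_that("separable classes are learned to >= 0.99 train accuracy", {
  tr <- make_separable_blocks(n_per_class = 12, K = 6, offset = 1,
                              noise = 0.2, seed = 7)
  std <- standardize_blocks(tr)
  cfg <- tiny_cfg(epochs = 70L, seed = 8)
  fit <- train_model(build_model(cfg), std$train)
  expect_gte(tail(fit$history$train_accuracy, 1), 0.99)
  expect_equal(nrow(fit$history), 70L)
  expect_true(all(fit$history$train_accuracy >= 0 &
                  fit$history$train_accuracy <= 1))
})

test_that("training is bit-reproducible under a fixed seed", {
  tr <- make_separable_blocks(n_per_class = 6, K = 4, seed = 9)
  std <- standardize_blocks(tr)
  cfg <- tiny_cfg(K = 4L, epochs = 8L, seed = 11)
  f1 <- train_model(build_model(cfg), std$train, std$train)
  f2 <- train_model(build_model(cfg), std$train, std$train)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$weights, f2$model$weights)
})

test_that("a single batch can be overfitted to near-zero loss", {
  tr <- make_separable_blocks(n_per_class = 4, K = 6, offset = 0.5,
                              noise = 0.5, seed = 12)
  std <- standardize_blocks(tr)
  cfg <- tiny_cfg(epochs = 200L, seed = 13)
  fit <- train_model(build_model(cfg), std$train)
  expect_lt(tail(fit$history$train_loss, 1), 0.01)
})

test_that("held-out separable blocks classify above 0.95 after training", {
  tr <- make_separable_blocks(n_per_class = 12, K = 6, offset = 1,
                              noise = 0.2, seed = 14)
  te <- make_separable_blocks(n_per_class = 10, K = 6, offset = 1,
                              noise = 0.2, seed = 15)
  std <- standardize_blocks(tr, te)
  fit <- train_model(build_model(tiny_cfg(epochs = 70L, seed = 16)),
                     std$train)
  pr <- predict_blocks(fit$model, std$other)
  truth <- vapply(std$other$blocks, `[[`, 0L, "class_label")
  expect_gte(mean(pr$labels == truth), 0.95)
})

test_that("model input contracts are enforced", {
  m <- build_model(tiny_cfg(seed = 17))
  wrong <- make_separable_blocks(n_per_class = 2, K = 5, seed = 18)
  expect_error(predict_blocks(m, wrong), "does not match model input")
  one_class <- make_separable_blocks(n_per_class = 3, K = 6, seed = 19)
  for (i in seq_along(one_class$blocks)) one_class$blocks[[i]]$class_label <- 1L
  expect_error(train_model(m, one_class), "single class")
  expect_error(model_config("multiscale", input_shape = c(3, 3, 6)),
               "exceeds block size")
  expect_error(model_config(kernel_bank = list(c(2, 3, 3))), "odd")
})

test_that("majority voting amplifies block accuracy when errors are iid", {
  set.seed(20)
  p_err <- 0.3
  n_seeds <- 400
  block_acc <- 0
  correct <- 0
  n_blocks_total <- 0
  for (i in seq_len(n_seeds)) {
    truth <- sample(1:2, 1)
    nb <- sample(c(5, 7, 9), 1)  # odd: no ties
    votes <- ifelse(runif(nb) < p_err, 3L - truth, truth)
    n_blocks_total <- n_blocks_total + nb
    block_acc <- block_acc + sum(votes == truth)
    correct <- correct + (vote_seed(votes)$voted_class == truth)
  }
  expect_gt(correct / n_seeds, block_acc / n_blocks_total)
})
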