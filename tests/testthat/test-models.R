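test_that("convolution forward matches hand values and the loop oracle", {
  expect_equal(conv1d_forward(matrix(c(1, 2, 3, 4), 1),
                              array(c(1, 0, -1), c(1, 3, 1))),
               c(-2, -2))
  # zero kernels + bias through the sigmoid unit
  z <- conv1d_forward(matrix(rnorm(20), 2), array(0, c(2, 3, 4)),
                      biases = c(-1, 0, 1, 2), activation = "sigmoid")
  expect_equal(z, matrix(rep(1 / (1 + exp(-c(-1, 0, 1, 2))), 8), 4, 8),
               tolerance = 1e-12)

  set.seed(4)
  x <- matrix(rnorm(8 * 32), 8, 32)
  w <- array(rnorm(8 * 5 * 3), c(8, 5, 3))
  b <- rnorm(3)
  expect_lt(max(abs(conv1d_forward(x, w, b) - naive_conv1d(x, w, b))), 1e-10)
  expect_error(conv1d_forward(matrix(rnorm(4), 1), array(1, c(1, 9, 1))),
               "exceeds input length")
  expect_error(conv1d_forward(matrix(rnorm(20), 2), array(1, c(3, 3, 1))),
               "channels")
})

test_that("bilstm output obeys the shape contract and reversal symmetry", {
  wts <- init_bilstm_weights(3, 4, seed = 2)
  x <- matrix(rnorm(3 * 6), 3, 6)
  y <- bilstm_forward(x, wts)
  expect_equal(dim(y), c(8L, 6L))

  # running the swapped weights on the time-reversed input and re-reversing
  # exchanges the two directional halves exactly
  y2 <- bilstm_forward(x[, 6:1], list(forward = wts$backward,
                                      backward = wts$forward))[, 6:1]
  expect_identical(y[1:4, ], y2[5:8, ])
  expect_identical(y[5:8, ], y2[1:4, ])
  expect_error(bilstm_forward(matrix(numeric(0), 3, 0), wts), "empty")
})

test_that("bilstm agrees with a step-by-step scalar recurrence", {
  wts <- init_bilstm_weights(2, 3, seed = 5)
  x <- ppgfatigue:::with_seed(6, matrix(rnorm(10), 2, 5))
  y <- bilstm_forward(x, wts)
  fwd <- naive_lstm(x, wts$forward$wx, wts$forward$wh, wts$forward$b)
  bwd <- naive_lstm(x[, 5:1], wts$backward$wx, wts$backward$wh,
                    wts$backward$b)[, 5:1]
  expect_lt(max(abs(y - rbind(fwd, bwd))), 1e-8)
})

test_that("scaled softmax is a shift-invariant probability map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(log(c(1, 3))), c(0.25, 0.75))
  expect_gt(softmax(c(1, 2), beta = 100)[2], 0.999)
  set.seed(7)
  z <- rnorm(11)
  expect_lt(abs(sum(softmax(z, 2.5)) - 1), 1e-12)
  expect_equal(softmax(z + 17, 2.5), softmax(z, 2.5), tolerance = 1e-12)
  expect_equal(softmax(c(1000, 1001)), softmax(c(0, 1)))  # overflow-safe
  zm <- matrix(rnorm(6), 2)
  expect_equal(colSums(softmax(zm)), rep(1, 3), tolerance = 1e-12)
  # monotone in each coordinate
  expect_gt(softmax(c(1.5, 2))[1], softmax(c(1, 2))[1])
})

test_that("the SGD update follows the decay/gradient/momentum decomposition", {
  expect_equal(sgd_step(0, 2, 0, lr = 0.1, batch_size = 1)$delta, -0.2)
  expect_equal(sgd_step(5, 0, 1, lr = 0.1, momentum = 0.9)$delta, 0.9)
  r <- sgd_step(2, 0, 0, lr = 0.1, weight_decay = 0.5, n_train = 10)
  expect_equal(r$value, 2 * (1 - 0.1 * 0.5 / 10))
  # biases carry no decay term
  rb <- sgd_step(2, 0, 0, lr = 0.1, weight_decay = 0.5, n_train = 10,
                 bias = TRUE)
  expect_equal(rb$delta, 0)
  expect_error(sgd_step(matrix(0, 2, 2), matrix(0, 3, 3)), "shape mismatch")
})

test_that("SGD without momentum or decay descends a quadratic monotonically", {
  w <- 4
  losses <- numeric(20)
  delta <- 0
  for (i in 1:20) {
    losses[i] <- 0.5 * w^2
    s <- sgd_step(w, w, delta, lr = 0.5, batch_size = 1)
    w <- s$value
    delta <- s$delta
  }
  expect_true(all(diff(losses) <= 0))
})

test_that("reference extractors meet the printed shape contracts", {
  ext_r <- build_extractor("resnet", reference_model_config("resnet_bilstm"))
  expect_equal(ext_r$out_channels, 15L)
  expect_equal(ext_r$steps, 132L)
  y <- extractor_forward(ext_r, array(rnorm(2112), c(1, 2112, 1)))
  expect_equal(dim(y)[1:2], c(15L, 264L))  # double window, double steps

  ext_x <- build_extractor("xception",
                           reference_model_config("xception_bilstm"))
  expect_equal(ext_x$out_channels, 64L)
  expect_equal(ext_x$steps, 132L)
})

test_that("extractor layer counting matches the configured totals", {
  count_weighted <- function(ext) {
    sum(vapply(ext$layers, function(l) {
      switch(l$type,
             conv = 1L, dwconv = 1L,
             resblock = 2L,            # two main-path convolutions
             xsep = 2L,                # depthwise + pointwise
             0L)
    }, integer(1)))
  }
  for (L in c(21L, 26L, 31L, 36L, 41L)) {
    ext <- build_extractor("resnet", model_config(layers = L, kernels = 8,
                                                  kernel_size = 7))
    expect_equal(count_weighted(ext), L)
  }
  for (L in c(31L, 34L, 37L, 40L, 43L)) {
    ext <- build_extractor("xception", model_config(layers = L, kernels = 8,
                                                    kernel_size = 9))
    expect_equal(count_weighted(ext), L)
  }
})

test_that("training is seeded, loss-decreasing and fits a separable toy set", {
  w <- toy_windows()
  cfg <- model_config(layers = 4, kernels = 6, kernel_size = 5,
                      bilstm_hidden = 8, epochs = 25, batch_size = 8,
                      seed = 1)
  fit <- train_model(w, cfg)
  expect_equal(nrow(fit$history), 25)
  expect_lt(fit$history$loss[25], fit$history$loss[1])
  pred <- predict(fit, w)
  expect_equal(mean(pred$.pred == w$label), 1.0)
  expect_equal(pred$p_fatigue + pred$p_non_fatigue, rep(1, nrow(w)),
               tolerance = 1e-12)

  fit2 <- train_model(w, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(ppgfatigue:::tree_flatten(
                     ppgfatigue:::params_of(fit$layers[[1]])),
                   ppgfatigue:::tree_flatten(
                     ppgfatigue:::params_of(fit2$layers[[1]])))

  expect_error(train_model(w[w$label == "fatigue", ], cfg), "single class")
  expect_error(predict(fit, toy_windows(len = 32)), "shape mismatch")
})

test_that("an untrained symmetric model is near-uninformative", {
  w <- toy_windows(n_per_class = 4)
  cfg <- model_config(layers = 4, kernels = 4, kernel_size = 5,
                      bilstm_hidden = 4, epochs = 1,
                      learning_rate = 1e-9, seed = 3)
  fit <- train_model(w, cfg)
  pred <- predict(fit, w)
  expect_true(all(abs(pred$p_fatigue - 0.5) < 0.2))
})

test_that("backpropagation matches finite differences on a 2-window batch", {
  worst_r <- gradcheck_model(model_config(family = "resnet_bilstm",
                                          layers = 5, kernels = 3,
                                          kernel_size = 5, bilstm_hidden = 3,
                                          seed = 7))
  expect_lt(worst_r, 1e-4)
  worst_x <- gradcheck_model(model_config(family = "xception_bilstm",
                                          layers = 7, kernels = 3,
                                          kernel_size = 5, bilstm_hidden = 3,
                                          seed = 8))
  expect_lt(worst_x, 1e-4)
})
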