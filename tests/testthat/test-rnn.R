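tiny_hp <- hyperparameter_set(0.01, 0.05, 12, 1, 4)

test_that("architecture follows the hyperparameters and init is seeded", {
  hp <- decode_position(c(0.007225, 0.150573, 58, 1, 12, 10, 9))
  m <- build_rnn(hp, lags = 15, seed = 1)
  expect_length(m$layers, 1L)
  expect_equal(dim(m$layers[[1]]$W), c(12, 12))
  expect_equal(dim(m$layers[[1]]$U), c(1, 12))

  hp3 <- hyperparameter_set(0.005, 0.1, 30, 3, c(8, 9, 10))
  m3 <- build_rnn(hp3, lags = 15, seed = 1)
  expect_length(m3$layers, 3L)
  expect_equal(dim(m3$layers[[2]]$U), c(8, 9))

  expect_identical(build_rnn(hp, seed = 7), build_rnn(hp, seed = 7))
})

test_that("all-zero weights give probability one half", {
  m <- build_rnn(tiny_hp, lags = 5, seed = 1)
  for (l in seq_along(m$layers)) {
    m$layers[[l]]$U[] <- 0; m$layers[[l]]$W[] <- 0; m$layers[[l]]$b[] <- 0
  }
  m$V[] <- 0; m$c <- 0
  expect_equal(rnn_forward(m, rnorm(5)), 0.5)
})

test_that("outputs are probabilities for any window", {
  set.seed(8)
  m <- build_rnn(tiny_hp, lags = 5, seed = 2)
  p <- rnn_forward(m, matrix(rnorm(1000 * 5, sd = 10), 1000, 5))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(rnn_forward(m, rnorm(4)), "lags")
})

test_that("a one-unit network reproduces the hand-rolled recurrence", {
  hp <- hyperparameter_set(0.01, 0, 30, 1, 1)
  m <- build_rnn(hp, lags = 2, seed = 1)
  m$layers[[1]]$U <- matrix(0.5)
  m$layers[[1]]$W <- matrix(0.3)
  m$layers[[1]]$b <- 0.1
  m$V <- matrix(0.8)
  m$c <- -0.2
  x <- c(0.4, -1.1)
  h1 <- tanh(0.1 + 0.5 * 0.4)
  h2 <- tanh(0.1 + 0.3 * h1 + 0.5 * -1.1)
  expect_equal(rnn_forward(m, x), 1 / (1 + exp(-(0.8 * h2 - 0.2))))
})

test_that("early-stopping patience is one third of the epoch budget", {
  expect_equal(early_stopping_patience(58), 20L)
  expect_equal(early_stopping_patience(30), 10L)
  expect_equal(early_stopping_patience(31), 11L)
})

test_that("training learns a separable problem and obeys its contract", {
  ds <- separable_windows(n = 400, lags = 5, seed = 3)
  sp <- chronological_split(ds, c(0.7, 0.1, 0.2))
  set.seed(5)
  run <- rnn_train(build_rnn(tiny_hp, lags = 5, seed = 5), sp$train, sp$val)
  expect_s3_class(run, "training_run")
  expect_lte(run$epochs_executed, run$epochs_requested)
  expect_equal(nrow(run$history), run$epochs_executed)
  acc <- mean(predict(run$model, sp$val$X) == sp$val$y)
  expect_gt(acc, 0.9)

  # restored best-epoch weights are no worse than the final epoch's
  final_val <- run$history$val_loss[run$epochs_executed]
  restored_val <- gipso:::bce_loss(rnn_forward(run$model, sp$val$X), sp$val$y)
  expect_lte(restored_val, final_val + 1e-9)

  expect_error(rnn_train(build_rnn(tiny_hp, lags = 5), sp$train,
                         structure(list(X = ds$X[0, ], y = integer(0),
                                        lags = 5),
                                   class = "windowed_dataset")),
               "non-empty")
})

test_that("training histories reproduce bit-for-bit under fixed seeds", {
  ds <- separable_windows(n = 120, lags = 5, seed = 4)
  sp <- chronological_split(ds)
  hp <- hyperparameter_set(0.01, 0.1, 4, 1, 4)
  r1 <- rnn_train(build_rnn(hp, lags = 5, seed = 9), sp$train, sp$val,
                  seed = 31)
  r2 <- rnn_train(build_rnn(hp, lags = 5, seed = 9), sp$train, sp$val,
                  seed = 31)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model, r2$model)
})

test_that("prediction thresholding is inclusive and monotone", {
  m <- build_rnn(tiny_hp, lags = 5, seed = 2)
  for (l in seq_along(m$layers)) {
    m$layers[[l]]$U[] <- 0; m$layers[[l]]$W[] <- 0; m$layers[[l]]$b[] <- 0
  }
  m$V[] <- 0; m$c <- 0
  expect_equal(predict(m, rnorm(5), threshold = 0.5), 1L)

  m2 <- build_rnn(tiny_hp, lags = 5, seed = 3)
  X <- matrix(rnorm(200 * 5), 200, 5)
  n_pos <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(th) sum(predict(m2, X, threshold = th)))
  expect_true(all(diff(n_pos) <= 0))
})
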