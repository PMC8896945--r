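test_that("weight encoding round-trips exactly and counts parameters correctly", {
  specs <- list(network_spec(22, 10, 4), network_spec(2, 4, 2),
                network_spec(5, 1, 3, activation = "logistic"))
  for (spec in specs) {
    expect_equal(n_weights(spec),
                 (spec$n_inputs + 1) * spec$n_hidden +
                   (spec$n_hidden + 1) * spec$n_outputs)
    set.seed(spec$n_inputs)
    for (k in 1:100) {
      w <- rnorm(n_weights(spec))
      expect_identical(encode_weights(spec, decode_weights(spec, w)), w)
    }
  }
})

test_that("all-zero weights give uniform scores and the documented tie-break", {
  spec <- network_spec(22, 10, 4)
  s <- ffnn_forward(spec, rep(0, n_weights(spec)), rnorm(22))
  expect_equal(as.numeric(s), rep(0.25, 4))

  m <- structure(list(spec = spec, weights = rep(0, n_weights(spec)),
                      center = rep(0, 22), scale = rep(1, 22),
                      labels = c("FORWARD", "RIGHT", "LEFT", "STOP"),
                      training = list()),
                 class = "eegcsa_model")
  expect_equal(predict(m, rnorm(22)), "FORWARD")  # exact tie -> lowest index
})

test_that("the forward pass matches hand arithmetic on a 1-1-2 toy network", {
  spec <- network_spec(1, 1, 2)
  # column-major, bias row first: W1 = [0.5; -1],
  # W2 column 1 = (bias 0.2, weight 2), column 2 = (bias -0.3, weight 1)
  w <- c(0.5, -1, 0.2, 2, -0.3, 1)
  x <- 0.7
  h <- tanh(0.5 - 1 * x)
  s <- c(0.2 + 2 * h, -0.3 + 1 * h)
  expected <- exp(s) / sum(exp(s))
  expect_equal(as.numeric(ffnn_forward(spec, w, x)), expected, tolerance = 1e-12)
})

test_that("scores are normalised and permuting output units permutes scores", {
  spec <- network_spec(6, 5, 4)
  set.seed(11)
  for (k in 1:20) {
    w <- rnorm(n_weights(spec), sd = 2)
    x <- matrix(rnorm(18), 3, 6)
    s <- ffnn_forward(spec, w, x)
    expect_equal(rowSums(s), rep(1, 3), tolerance = 1e-12)
    expect_true(all(s >= 0))

    ly <- decode_weights(spec, w)
    perm <- c(3, 1, 4, 2)
    ly$W2 <- ly$W2[, perm]
    s_perm <- ffnn_forward(spec, encode_weights(spec, ly), x)
    expect_equal(s_perm, s[, perm], tolerance = 1e-12)
  }
})

test_that("loss has its closed-form values at the reference points", {
  spec <- network_spec(3, 2, 4)
  set.seed(12)
  x <- matrix(rnorm(30), 10, 3)
  y <- rep(1:4, length.out = 10)
  expect_equal(ffnn_loss(spec, rep(0, n_weights(spec)), x, y), log(4))

  # zero weights predict class 1 everywhere; misclassification counts the rest
  y2 <- c(1, 1, 1, 1, 1, 1, 1, 2, 3, 4)
  expect_equal(ffnn_loss(spec, rep(0, n_weights(spec)), x, y2,
                         type = "misclassification"), 0.3)

  expect_error(ffnn_loss(spec, rep(0, n_weights(spec)),
                         matrix(numeric(0), 0, 3), integer(0)), "empty")
})

test_that("cross-entropy tends to zero for a perfectly confident scorer", {
  spec <- network_spec(1, 1, 2)
  # large weights drive the correct class score toward 1:
  # h = tanh(5x); output activations -20h and +20h
  w <- c(0, 5, 0, -20, 0, 20)
  x <- matrix(c(-1, 1), 2, 1)
  y <- c(1, 2)
  expect_lt(ffnn_loss(spec, w, x, y), 1e-6)
})

test_that("crow search solves XOR through the network", {
  xor_x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  xor_y <- factor(c("A", "B", "B", "A"))
  ok <- 0
  for (s in 1:10) {
    m <- ffnn_train(xor_x, xor_y, spec = network_spec(2, 4, 2),
                    standardize = FALSE, flock_size = 20,
                    max_iterations = 150, seed = s)
    if (all(predict(m, xor_x) == as.character(xor_y))) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("well-separated Gaussian blobs in 22 dimensions are classified almost perfectly", {
  set.seed(13)
  centers <- matrix(rnorm(4 * 22, sd = 4), 4, 22)
  n_per <- 30
  x <- do.call(rbind, lapply(1:4, function(k) {
    matrix(rnorm(n_per * 22), n_per, 22) + matrix(centers[k, ], n_per, 22,
                                                  byrow = TRUE)
  }))
  y <- factor(rep(c("FORWARD", "RIGHT", "LEFT", "STOP"), each = n_per))
  train <- as.vector(sapply(0:3, function(k) k * n_per + 1:20))
  test <- setdiff(seq_len(nrow(x)), train)
  m <- ffnn_train(x[train, ], y[train], max_iterations = 200, seed = 3)
  expect_gt(mean(predict(m, x[test, ]) == as.character(y[test])), 0.95)
})

test_that("training is reproducible and honours a zero-iteration budget", {
  set.seed(14)
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(c("A", "B"), 10))
  m1 <- ffnn_train(x, y, spec = network_spec(2, 3, 2), max_iterations = 50,
                   seed = 5)
  m2 <- ffnn_train(x, y, spec = network_spec(2, 3, 2), max_iterations = 50,
                   seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$training$final_loss, m2$training$final_loss)

  m0 <- ffnn_train(x, y, spec = network_spec(2, 3, 2), max_iterations = 0,
                   seed = 5)
  expect_equal(m0$training$evaluations, 20)  # flock size only
  expect_equal(m0$training$final_loss, m0$training$fitness_history[1])
})

test_that("dimension mismatches are labelled errors", {
  spec <- network_spec(4, 2, 3)
  expect_error(ffnn_forward(spec, rep(0, n_weights(spec)), rnorm(5)), "features")
  expect_error(ffnn_forward(spec, rep(0, 3), rnorm(4)), "length")
  m <- ffnn_train(matrix(rnorm(20), 10, 2), factor(rep(c("A", "B"), 5)),
                  spec = network_spec(2, 2, 2), max_iterations = 5, seed = 1)
  expect_error(predict(m, rnorm(3)), "features")
})

test_that("models survive a JSON round-trip", {
  set.seed(15)
  x <- matrix(rnorm(60), 20, 3)
  y <- factor(rep(c("LEFT", "STOP"), 10))
  m <- ffnn_train(x, y, spec = network_spec(3, 2, 2), max_iterations = 20,
                  seed = 2)
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$center, unname(m$center))
  expect_identical(predict(m2, x), predict(m, x))
})
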