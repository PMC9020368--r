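test_that("forward pass matches a hand-expanded evaluation", {
  # 2 -> 2 -> 2 with small integer weights, checked against the oracle
  params <- list(W1 = matrix(c(1, -1, 2, 0), 2, 2),
                 B1 = c(0.5, -0.5),
                 W2 = matrix(c(1, 2, -1, 1), 2, 2),
                 B2 = c(0, 1))
  for (i in 1:2) {
    x <- c(0, 0); x[i] <- 1
    expect_equal(
      as.numeric(net_forward(params, inputs = i, sigmoid_output = FALSE)),
      oracle_forward(params$W1, params$B1, params$W2, params$B2, x,
                     sigmoid_output = FALSE), tolerance = 1e-12)
    expect_equal(
      as.numeric(net_forward(params, inputs = i, sigmoid_output = TRUE)),
      oracle_forward(params$W1, params$B1, params$W2, params$B2, x,
                     sigmoid_output = TRUE), tolerance = 1e-12)
  }
  # all-zero parameters: hidden sits at sigmoid(0) = 0.5, output at -B2
  zero <- list(W1 = matrix(0, 3, 2), B1 = numeric(2),
               W2 = matrix(0, 2, 4), B2 = c(1, 2, 3, 4))
  expect_equal(as.numeric(net_forward(zero, inputs = 1,
                                      sigmoid_output = FALSE)),
               -c(1, 2, 3, 4))
  # saturating positive bias silences the hidden layer
  sat <- list(W1 = matrix(1, 3, 2), B1 = c(1e4, 1e4),
              W2 = matrix(1, 2, 4), B2 = numeric(4))
  expect_equal(as.numeric(net_forward(sat, inputs = 2,
                                      sigmoid_output = FALSE)),
               numeric(4), tolerance = 1e-9)
})

test_that("forward validates shapes and one-hot inputs", {
  params <- list(W1 = matrix(0, 3, 2), B1 = numeric(2),
                 W2 = matrix(0, 2, 4), B2 = numeric(4))
  expect_error(net_forward(params, inputs = 5), "out of range")
  expect_error(net_forward(params, inputs = matrix(c(1, 1, 0), 1)), "one-hot")
  expect_error(net_forward(params, inputs = 1, clamp_units = 3),
               "hidden-unit index")
})

test_that("binarize thresholds at 0.5 with ties mapped upward", {
  expect_identical(binarize(c(0.49, 0.51)), c(0L, 1L))
  expect_identical(binarize(0.5), 1L)
  expect_identical(binarize(c(0, 1, 1, 0)), c(0L, 1L, 1L, 0L))  # idempotent
  m <- matrix(c(0.2, 0.8, 0.5, -3), 2, 2)
  expect_identical(binarize(m), matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_error(binarize(c(1, NaN)), "finite")
})

test_that("training is deterministic and learns unbottlenecked instances", {
  b <- random_behaviors(10, 10, 3, seed = 5)
  f1 <- bottleneck_net(b, R = 10, epochs = 2000, seed = 9)
  f2 <- bottleneck_net(b, R = 10, epochs = 2000, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_equal(f1$fraction_learned, 1.0)
  # trivial single-pattern instance
  f0 <- bottleneck_net(matrix(1, 1, 1), R = 1, epochs = 500, seed = 1)
  expect_equal(f0$fraction_learned, 1.0)
  # capacity sanity at R >= M for a larger small instance
  b20 <- random_behaviors(20, 20, 5, seed = 2)
  expect_equal(bottleneck_net(b20, R = 20, epochs = 3000,
                              seed = 3)$fraction_learned, 1.0)
})

test_that("severe bottlenecks yield partial learning, not failure", {
  b <- random_behaviors(50, 50, 8, seed = 21)
  f <- bottleneck_net(b, R = 2, epochs = 2000, seed = 1)
  expect_true(f$fraction_learned >= 0 && f$fraction_learned < 0.5)
  expect_true(all(is.finite(f$loss_trace$loss)))
})

test_that("loss decreases in trend and mini-batch mode also learns", {
  b <- random_behaviors(12, 12, 3, seed = 6)
  f <- bottleneck_net(b, R = 12, epochs = 2000, seed = 2, batch_size = 4)
  expect_equal(f$fraction_learned, 1.0)
  tr <- f$loss_trace$loss
  expect_lt(tr[length(tr)], tr[1] / 10)
  # trend, not monotonicity: compare means of first and last quarter
  q <- length(tr) %/% 4
  expect_lt(mean(tr[(length(tr) - q):length(tr)]), mean(tr[1:q]))
})

test_that("fraction_learned scores whole rows, matching the row oracle", {
  f <- trained_fixture(N = 12, M = 12, k = 3, R = 5, epochs = 1200)
  bin <- predict(f)
  expect_equal(fraction_learned(f), oracle_fraction(bin, unclass(f$target)))
  # a network outputting all zeros scores 0 against any k > 0 target
  zero <- list(W1 = matrix(0, 12, 3), B1 = rep(1e4, 3),
               W2 = matrix(0, 3, 12), B2 = rep(1, 12),
               target = f$target, config = list(sigmoid_output = FALSE))
  expect_equal(fraction_learned(zero, f$target), 0)
  # exact reproduction scores 1 (tautological oracle route)
  expect_equal(oracle_fraction(unclass(f$target), unclass(f$target)), 1)
})

test_that("hidden activations binarize harder as the bottleneck tightens", {
  # distance of hidden activations from {0,1}, averaged over 5 seeds, drops
  # when R shrinks toward the critical region on a fixed instance
  b <- random_behaviors(20, 20, 4, seed = 13)
  dist_at <- function(R) mean(vapply(1:5, function(s)
    summary(bottleneck_net(b, R = R, epochs = 3000,
                           seed = s))$hidden_saturation, numeric(1)))
  expect_lt(dist_at(8), dist_at(20))
})

test_that("invalid training configurations are rejected", {
  b <- random_behaviors(5, 5, 2, seed = 1)
  expect_error(bottleneck_net(b, R = 0), "positive integer")
  expect_error(bottleneck_net(b, R = 2, epochs = 0), "configuration")
  expect_error(bottleneck_net(b, R = 2, learning_rate = -1), "configuration")
  expect_error(bottleneck_net(b, R = 2, momentum = 1), "configuration")
  expect_error(bottleneck_net(matrix(2, 2, 2), R = 1), "binary")
})

test_that("trained networks round-trip through the JSON archive", {
  f <- trained_fixture(N = 8, M = 8, k = 2, R = 4, epochs = 800)
  file <- withr::local_tempfile(fileext = ".json")
  write_network(f, file)
  g <- read_network(file)
  expect_equal(g$W1, f$W1, tolerance = 1e-12)
  expect_equal(g$B2, f$B2, tolerance = 1e-12)
  expect_identical(g$binary, f$binary)
  expect_equal(g$fraction_learned, f$fraction_learned)
  expect_identical(binarize(net_forward(g)), binarize(net_forward(f)))
})
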