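test_that("integrated gradients is exact for linear models at any step count", {
  lin <- mlp_net(w2 = c(2, -1, 0.5), b2 = 3)
  x <- c(3, 4, -2)
  for (steps in c(1, 3, 64))
    expect_equal(integrated_gradients(lin, x, steps = steps)$values,
                 c(2, -1, 0.5) * x, tolerance = 1e-12)
  expect_error(integrated_gradients(lin, x, steps = 0), "steps")
})

test_that("constant models yield all-zero maps from every method", {
  const <- mlp_net(w2 = c(0, 0, 0), b2 = 1.3)
  x <- c(1, -2, 3)
  expect_equal(integrated_gradients(const, x)$values, c(0, 0, 0))
  expect_equal(guided_backprop(const, x)$values, c(0, 0, 0))
  expect_equal(reference_attribution(const, x, seed = 1)$values, c(0, 0, 0))
})

test_that("integrated gradients satisfies completeness on random ReLU nets", {
  for (s in 1:10) {
    net <- random_relu_net(d = 8, h = 8, seed = s)
    set.seed(100 + s)
    x <- rnorm(8)
    attr <- integrated_gradients(net, x, steps = 512)
    delta <- model_output(net, x) - model_output(net, numeric(8))
    expect_lt(abs(sum(attr$values) - delta) / abs(delta), 1e-3)
  }
})

test_that("guided backprop masks by pre-activation and incoming signal", {
  # single unit y = ReLU(w . x) with a negative pre-activation: zero map
  w <- c(1, -2)
  net <- mlp_net(w2 = 1, W1 = matrix(w, 1), b1 = 0)
  x <- c(-1, 1)            # w . x = -3 < 0
  expect_equal(guided_backprop(net, x)$values, c(0, 0))
  # ReLU-free linear model with nonnegative weights: map equals the gradient
  lin <- mlp_net(w2 = c(1, 2), b2 = 0)
  expect_equal(guided_backprop(lin, c(5, -3))$values, c(1, 2))
  # nonnegativity holds for arbitrary nets and inputs
  set.seed(9)
  for (i in 1:20) {
    net <- random_relu_net(d = 6, h = 5, seed = 200 + i)
    expect_true(all(guided_backprop(net, rnorm(6))$values >= 0))
  }
})

test_that("reference attribution satisfies summation-to-delta", {
  # background equal to the input: zero delta, zero attribution
  net <- random_relu_net(d = 6, h = 6, seed = 4)
  set.seed(5); x <- rnorm(6)
  expect_equal(reference_attribution(net, x, background = list(x))$values,
               numeric(6), tolerance = 1e-12)
  # linear model against a zero reference: w_j * x_j
  lin <- mlp_net(w2 = c(1, -1, 2), b2 = 5)
  expect_equal(reference_attribution(lin, c(2, 3, 4),
                                     background = list(numeric(3)))$values,
               c(2, -3, 8), tolerance = 1e-12)
  # toy ReLU net, 8 references
  set.seed(6)
  bg <- lapply(1:8, function(i) rnorm(6, 0, 0.5))
  attr <- reference_attribution(net, x, background = bg, steps = 64)
  delta <- model_output(net, x) -
    mean(vapply(bg, function(r) model_output(net, r), numeric(1)))
  expect_lt(abs(sum(attr$values) - delta) / abs(delta), 1e-2)
  expect_error(reference_attribution(net, x, background = list()), "non-empty")
})

test_that("attention conversion takes absolute values and is idempotent", {
  a <- ppgexplain:::new_attribution(c(-1, 2, 0), "integrated_gradients")
  expect_equal(as.numeric(to_attention(a)), c(1, 2, 0))
  expect_equal(as.numeric(to_attention(to_attention(a))), c(1, 2, 0))
  expect_equal(as.numeric(to_attention(ppgexplain:::new_attribution(
    c(0, 0), "guided"))), c(0, 0))
  expect_identical(attr(to_attention(a), "method"), "integrated_gradients")
})

test_that("column reduction takes abs-then-max and resizes nearest-neighbor", {
  expect_equal(reduce_columns(rbind(c(1, 0, 2), c(0, 3, 1))), c(1, 3, 2))
  expect_equal(reduce_columns(matrix(c(5, 1, 4), 1)), c(5, 1, 4))
  expect_equal(reduce_columns(matrix(c(-2, -1), 1)), c(2, 1))
  # nearest-neighbor upscaling from 3 columns to 5 samples
  expect_equal(reduce_columns(matrix(c(1, 2, 3), 1), n = 5),
               c(1, 1, 2, 3, 3))
  expect_error(reduce_columns(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("the CNN honours the attribution contracts", {
  n <- 241
  m <- tiny_cnn(n, seed = 8)
  set.seed(12); x <- rnorm(n)
  # input gradient matches central finite differences
  g <- model_input_gradient(m, x)
  for (j in c(1, 60, 200)) {
    xp <- x; xp[j] <- xp[j] + 1e-5
    xm <- x; xm[j] <- xm[j] - 1e-5
    fd <- (model_output(m, xp) - model_output(m, xm)) / 2e-5
    expect_equal(g[j], fd, tolerance = 1e-5)
  }
  # completeness of integrated gradients against two forward passes
  attr <- integrated_gradients(m, x, steps = 256)
  delta <- model_output(m, x) - model_output(m, numeric(n))
  expect_lt(abs(sum(attr$values) - delta), 1e-2 * max(abs(delta), 1e-3))
  # guided map nonnegative, same shape as the input
  gmap <- guided_backprop(m, x)
  expect_length(gmap$values, n)
  expect_true(all(gmap$values >= 0))
})
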