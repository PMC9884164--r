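test_that("valid-convolution and pooling arithmetic is layer-exact", {
  arch <- cnn_architecture()
  sh <- forward_shapes(arch)
  L <- 3000
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    L <- if (ly$type == "conv") L - ly$k + 1 else L %/% 2
    expect_identical(sh$length[i + 1], as.integer(L))
  }
  expect_identical(tail(sh$length, 1), 38L)
  # the printed odd -> even steps force floor division
  expect_identical(741L %/% 2L, 370L)
  expect_error(forward_shapes(arch, input_len = 10), "too short")
})

test_that("segments decimate to a z-normalized length-3000 input", {
  seg <- make_segment("N", seed = 2)$segment
  z <- prepare_cnn_input(seg$samples, seg$fs)
  expect_length(z, 3000)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(mean(z^2), 1, tolerance = 1e-8)
  expect_identical(prepare_cnn_input(rep(4, 9000)), rep(0, 3000))
  expect_warning(prepare_cnn_input(rnorm(7000)), "polyphase")
})

test_that("analytic gradients agree with finite differences", {
  arch <- cnn_architecture(input_len = 40, n_features = 5,
                           kernel_sizes = c(5, 3), channels = c(2, 3))
  set.seed(99)
  X <- matrix(rnorm(3 * 40), 3, 40)
  y <- c(1L, 2L, 1L)
  params <- afusion:::cnn_init(arch, n_classes = 2, seed = 7)
  lg <- afusion:::cnn_loss_grad(arch, params, X, y)
  eps <- 1e-5
  for (nm in c("W1", "b1", "W3", "W_fc", "W_head", "b_head")) {
    p <- params[[nm]]
    for (idx in sample(length(p), min(4, length(p)))) {
      pp <- params; pp[[nm]][idx] <- p[idx] + eps
      pm <- params; pm[[nm]][idx] <- p[idx] - eps
      num <- (afusion:::cnn_loss_grad(arch, pp, X, y)$loss -
              afusion:::cnn_loss_grad(arch, pm, X, y)$loss) / (2 * eps)
      ana <- lg$grads[[nm]][idx]
      expect_equal(ana, num, tolerance = 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("training lowers the loss deterministically", {
  set.seed(5)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 100), ncol = 100),
             matrix(rnorm(n / 2 * 100, mean = 1.5), ncol = 100))
  y <- rep(c("N", "~"), each = n / 2)
  arch <- cnn_architecture(input_len = 100, n_features = 8,
                           kernel_sizes = c(5, 3), channels = c(4, 4))
  m1 <- train_cnn(X, y, arch = arch, epochs = 8, batch_size = 8, seed = 3)
  expect_lt(tail(m1$history, 1), m1$history[1])
  m2 <- train_cnn(X, y, arch = arch, epochs = 8, batch_size = 8, seed = 3)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)

  m0 <- train_cnn(X, y, arch = arch, epochs = 3, batch_size = 8, lr = 0, seed = 3)
  expect_equal(m0$history[1], tail(m0$history, 1), tolerance = 1e-9)

  expect_error(train_cnn(X, rep("N", n), arch = arch), "2 classes")
})

test_that("abstract features are 38-dimensional, deterministic and informative", {
  segs <- c(lapply(1:12, function(s) make_segment("N", seed = s)$segment),
            lapply(1:12, function(s) make_segment("~", seed = s)$segment))
  X <- t(vapply(segs, function(s) prepare_cnn_input(s$samples, s$fs),
                numeric(3000)))
  y <- rep(c("N", "~"), each = 12)
  model <- train_cnn(X, y, epochs = 4, batch_size = 8, seed = 2)
  ab <- extract_abstract(model, X)
  expect_identical(dim(ab), c(24L, 38L))
  expect_true(all(is.finite(ab)))
  expect_identical(extract_abstract(model, X[1, ]),
                   extract_abstract(model, X[1, , drop = FALSE]))
  expect_gt(max(abs(ab[1, ] - ab[13, ])), 0)
  # a linear probe separates clean from noise-dominated segments
  train_i <- c(1:8, 13:20)
  test_i <- setdiff(1:24, train_i)
  lda_fit <- suppressWarnings(MASS::lda(ab[train_i, ], grouping = y[train_i]))
  pred <- predict(lda_fit, ab[test_i, ])$class
  expect_gt(mean(pred == y[test_i]), 0.9)
})
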