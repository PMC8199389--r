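test_that("configuration guards reject infeasible networks", {
  expect_error(odcnn_config(depth = 0), "depth")
  expect_error(odcnn_config(kernel_size = 4), "odd")
  expect_error(odcnn_config(learning_rate = 0), "learning_rate")
  # depth 5 x kernel 7 shrinks a 13-length input away without padding
  expect_error(odcnn_init(odcnn_config(depth = 5, kernel_size = 7,
                                       padding = "valid"), input_dim = 13),
               "infeasible")
  # but is feasible with `same` padding
  expect_silent(m <- odcnn_init(odcnn_config(depth = 5, kernel_size = 7),
                                input_dim = 13))
  expect_equal(m$layer_lengths, rep(13L, 5))
})

test_that("forward propagation has the contracted shape and zero fixpoint", {
  cfg <- odcnn_config(depth = 2, kernel_size = 3, n_filters = 4,
                      mlp_hidden = 6, seed = 1)
  m <- odcnn_init(cfg, input_dim = 13, n_classes = 4)
  fw <- odcnn_forward(m, rnorm(13))
  expect_length(fw$scores, 4)
  # all-zero weights and biases give all-zero scores
  z <- m
  for (g in seq_along(z$conv)) {
    z$conv[[g]]$W[] <- 0; z$conv[[g]]$b[] <- 0
  }
  z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
  expect_equal(odcnn_forward(z, rnorm(13))$scores, rep(0, 4))
  expect_error(odcnn_forward(m, rnorm(12)), "input layer")
})

test_that("a single identity-like conv layer propagates by hand", {
  # one conv group, 1 filter, kernel (0,1,0): convolution is the identity
  # on the interior; ELU on positive inputs is the identity too
  cfg <- odcnn_config(depth = 1, kernel_size = 3, n_filters = 1,
                      mlp_hidden = 2, seed = 1)
  m <- odcnn_init(cfg, input_dim = 5, n_classes = 4)
  m$conv[[1]]$W[] <- c(0, 1, 0)
  m$conv[[1]]$b[] <- 0
  x <- c(1, 2, 3, 4, 5)
  fw <- odcnn_forward(m, x)
  # hand propagation: conv output = x, then the two MLP layers
  h <- elu(as.vector(x %*% m$W1) + m$b1)
  expect_equal(fw$scores, as.vector(h %*% m$W2) + m$b2, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(20)
  archs <- list(
    list(depth = 1, kernel_size = 3, pool_factor = 1, padding = "same"),
    list(depth = 2, kernel_size = 3, pool_factor = 2, padding = "same"),
    list(depth = 2, kernel_size = 5, pool_factor = 1, padding = "same"),
    list(depth = 1, kernel_size = 3, pool_factor = 2, padding = "valid"))
  for (a in archs) {
    cfg <- do.call(odcnn_config, c(a, list(n_filters = 3, mlp_hidden = 4,
                                           seed = 77)))
    m <- odcnn_init(cfg, input_dim = 13, n_classes = 4)
    x <- rnorm(13); u <- c(0, 0, 1, 0)
    gr <- odcnn_backward(m, odcnn_forward(m, x)$cache, u)
    for (probe in 1:5) {
      g <- sample(length(m$conv), 1)
      wi <- sample(length(m$conv[[g]]$W), 1)
      fd <- fd_grad(m, x, u,
                    function(mm) mm$conv[[g]]$W[wi],
                    function(mm, v) { mm$conv[[g]]$W[wi] <- v; mm })
      expect_equal(gr$conv[[g]]$W[wi], fd, tolerance = 1e-4)
      bi <- sample(length(m$conv[[g]]$b), 1)
      fd <- fd_grad(m, x, u,
                    function(mm) mm$conv[[g]]$b[bi],
                    function(mm, v) { mm$conv[[g]]$b[bi] <- v; mm })
      expect_equal(gr$conv[[g]]$b[bi], fd, tolerance = 1e-4)
      wi <- sample(length(m$W1), 1)
      fd <- fd_grad(m, x, u,
                    function(mm) mm$W1[wi],
                    function(mm, v) { mm$W1[wi] <- v; mm })
      expect_equal(gr$W1[wi], fd, tolerance = 1e-4)
    }
    # zero delta at the output gives all-zero gradients
    fw <- odcnn_forward(m, x)
    gr0 <- odcnn_backward(m, fw$cache, fw$scores)
    expect_equal(max(abs(unlist(gr0))), 0, tolerance = 1e-12)
  }
})

test_that("a single linear unit has the closed-form gradient", {
  # no conv contribution (zero kernels), identity-ish MLP: score_j =
  # sum_i W1[i,1] x_i ... use a 1-hidden-unit linear path on positive
  # pre-activations so ELU is the identity
  cfg <- odcnn_config(depth = 1, kernel_size = 1, n_filters = 1,
                      mlp_hidden = 1, seed = 3)
  m <- odcnn_init(cfg, input_dim = 4, n_classes = 4)
  m$conv[[1]]$W[] <- 1; m$conv[[1]]$b[] <- 0     # conv = identity
  x <- c(0.5, 1, 1.5, 2)                          # positive: ELU = id
  m$W1[] <- abs(m$W1)                             # keep hidden positive
  fw <- odcnn_forward(m, x)
  u <- c(1, 0, 0, 0)
  gr <- odcnn_backward(m, fw$cache, u)
  h <- sum(x * m$W1) + m$b1
  expect_equal(as.vector(gr$W2), 2 * (fw$scores - u) * h, tolerance = 1e-10)
  expect_equal(gr$b2, 2 * (fw$scores - u), tolerance = 1e-10)
})

test_that("SGD updates follow w <- w - eps * grad", {
  cfg <- odcnn_config(depth = 1, kernel_size = 3, n_filters = 2,
                      mlp_hidden = 3, seed = 5)
  m <- odcnn_init(cfg, input_dim = 13)
  x <- rnorm(13); u <- c(0, 1, 0, 0)
  gr <- odcnn_backward(m, odcnn_forward(m, x)$cache, u)
  expect_equal(odcnn_sgd_step(m, gr, 0), m)
  m2 <- odcnn_sgd_step(m, gr, 0.1)
  expect_equal(m2$W2, m$W2 - 0.1 * gr$W2, tolerance = 1e-12)
  expect_equal(m2$conv[[1]]$W, m$conv[[1]]$W - 0.1 * gr$conv[[1]]$W,
               tolerance = 1e-12)
  # two sequential updates with the same gradients equal one update of
  # the summed gradients (linearity of the update rule)
  m3 <- odcnn_sgd_step(odcnn_sgd_step(m, gr, 0.1), gr, 0.1)
  gr2 <- gr
  gr2$W1 <- 2 * gr$W1; gr2$b1 <- 2 * gr$b1
  gr2$W2 <- 2 * gr$W2; gr2$b2 <- 2 * gr$b2
  gr2$conv <- lapply(gr$conv, function(g) list(W = 2 * g$W, b = 2 * g$b))
  m4 <- odcnn_sgd_step(m, gr2, 0.1)
  expect_equal(m3$W2, m4$W2, tolerance = 1e-12)
  gr$W1[1] <- NaN
  expect_error(odcnn_sgd_step(m, gr, 0.1), "non-finite")
})

test_that("training solves a separable toy problem and is deterministic", {
  toy <- separable_toy()
  cfg <- odcnn_config(depth = 1, kernel_size = 3, n_filters = 4,
                      mlp_hidden = 8, learning_rate = 1e-3,
                      epochs = 200, seed = 31)
  fit <- odcnn(toy$x, toy$y, cfg)
  expect_equal(mean(predict(fit, toy$x) == toy$y), 1.0)
  fit2 <- odcnn(toy$x, toy$y, cfg)
  expect_identical(fit$W1, fit2$W1)
  expect_identical(fit$conv[[1]]$W, fit2$conv[[1]]$W)
  # the loss trend is downward: mean over last 10% < mean over first 10%
  lc <- fit$loss_curve
  k <- max(1, floor(length(lc) / 10))
  expect_lt(mean(tail(lc, k)), mean(head(lc, k)))
})

test_that("training reports divergence for an absurd learning rate", {
  toy <- separable_toy()
  cfg <- odcnn_config(depth = 1, kernel_size = 3, learning_rate = 10,
                      epochs = 30, seed = 31)
  expect_error(odcnn(toy$x, toy$y, cfg), "diverged")
  expect_error(odcnn(toy$x, rep(0L, nrow(toy$x)), cfg), "2 classes")
})

test_that("prediction exposes scores whose argmax is the label", {
  d <- small_dataset()
  fm <- emotion_feature_matrix(d)
  fit <- odcnn(fm$x, fm$y, odcnn_config(depth = 2, epochs = 25, seed = 17))
  sc <- predict(fit, fm$x, type = "score")
  expect_equal(dim(sc), c(nrow(fm$x), 4L))
  lab <- predict(fit, fm$x)
  expect_equal(lab, as.integer(apply(sc, 1, which.max) - 1L))
  expect_error(predict(fit, fm$x[, 1:12]), "features")
})

test_that("model serialization round-trips exactly", {
  toy <- separable_toy()
  fit <- odcnn(toy$x, toy$y, odcnn_config(depth = 1, epochs = 5, seed = 2))
  f <- tempfile(fileext = ".rds")
  write_odcnn(fit, f)
  back <- read_odcnn(f)
  expect_identical(back$W1, fit$W1)
  expect_identical(back$conv, fit$conv)
  expect_identical(predict(back, toy$x, type = "score"),
                   predict(fit, toy$x, type = "score"))
  saveRDS(list(format = "other"), f)
  expect_error(read_odcnn(f), "container")
  unlink(f)
})
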