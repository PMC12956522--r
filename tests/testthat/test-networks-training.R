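test_that("default architectures match the reference layer chains", {
  cfg <- neuron_config()
  mlp <- build_network(architecture_spec("mlp", 784, 10), cfg, seed = 1)
  shapes <- lapply(mlp$layers, function(l) dim(l$W))
  expect_equal(shapes, list(c(512, 784), c(256, 512), c(64, 256), c(10, 64)))
  expect_null(mlp$layers[[4]]$bn) # output layer has no normalization
  expect_false(is.null(mlp$layers[[1]]$bn))

  conv <- build_network(
    architecture_spec("conv", c(3, 32, 32), 10), cfg, seed = 1
  )
  expect_equal(purrr::map_chr(conv$layers, "type"),
               c("conv", "conv", "dense", "dense"))
  expect_equal(dim(conv$layers[[1]]$W), c(64, 3, 3, 3))
  expect_equal(dim(conv$layers[[2]]$W), c(128, 64, 3, 3))
  expect_true(conv$layers[[2]]$gap)
  expect_equal(dim(conv$layers[[3]]$W), c(64, 128))
  expect_equal(dim(conv$layers[[4]]$W), c(10, 64))

  # deterministic initialization under a seed
  expect_identical(
    build_network(architecture_spec("mlp", 20, 3, hidden = 5), cfg, seed = 9),
    build_network(architecture_spec("mlp", 20, 3, hidden = 5), cfg, seed = 9)
  )
})

test_that("an unexcited fresh network emits no output spikes", {
  cfg <- neuron_config(tau_m = 2, v_th = 1)
  net <- build_network(architecture_spec("mlp", 8, 3, hidden = 4), cfg, seed = 2)
  x <- matrix(0, 10, 8)
  out <- forward(net, x)
  expect_equal(unname(out$counts), rep(0, 3))
})

test_that("forward dynamics match an independent scalar simulation", {
  # hand-built 2-2-2 toy network with fixed weights, identity normalization
  cfg <- neuron_config(tau_m = 2, v_th = 0.6)
  net <- build_network(architecture_spec("mlp", 2, 2, hidden = 2), cfg, seed = 1)
  net$layers[[1]]$W <- matrix(c(0.8, -0.3, 0.2, 0.9), 2, 2)
  net$layers[[1]]$b <- c(0.05, -0.02)
  net$layers[[2]]$W <- matrix(c(1.1, 0.4, -0.5, 0.7), 2, 2)
  net$layers[[2]]$b <- c(0, 0.1)
  set.seed(8)
  x <- matrix(rbinom(20, 1, 0.5), 10, 2)
  got <- forward(net, x, record = TRUE)
  ref <- reference_mlp_forward(net, x)
  expect_equal(unname(got$counts), ref$counts)
  expect_equal(got$record[[1]], ref$layer_spikes[[1]])
  expect_equal(got$record[[2]], ref$layer_spikes[[2]])
})

test_that("label decoding takes the argmax with low-index tie-breaking", {
  expect_equal(predict_label(c(0.1, 0.9, 0.3)), 1L)
  expect_equal(predict_label(c(0.5, 0.5)), 0L)
  zero <- predict_label(c(0, 0, 0))
  expect_equal(as.integer(zero), 0L)
  expect_true(isTRUE(attr(zero, "degenerate")))
  expect_error(predict_label(numeric()), "class")
})

test_that("training is reproducible, and zero epochs is the identity", {
  task <- make_static_task(synthetic_task_config(
    n_classes = 2, train_per_class = 20, test_per_class = 5, seed = 15
  ))
  data <- encode_dataset(task$train, 5, seed = 1)
  spec <- architecture_spec("mlp", 144, 2, hidden = 8)
  net <- build_network(spec, neuron_config(), seed = 3)

  fit0 <- train_network(net, data, training_config(n_steps = 5, epochs = 0))
  expect_identical(fit0$network, net)
  expect_equal(nrow(fit0$history), 0)

  tc <- training_config(n_steps = 5, epochs = 2, seed = 4)
  fit1 <- train_network(net, data, tc)
  fit2 <- train_network(net, data, tc)
  expect_identical(fit1$network$layers, fit2$network$layers)
  expect_false(identical(fit1$network$layers, net$layers))
})

test_that("a separable two-class task trains to high accuracy quickly", {
  task <- make_static_task(synthetic_task_config(
    n_classes = 2, train_per_class = 100, test_per_class = 20, seed = 21
  ))
  data <- encode_dataset(task$train, 10, seed = 2)
  net <- build_network(architecture_spec("mlp", 144, 2, hidden = c(32, 16)),
                       neuron_config(tau_m = 2, v_th = 1), seed = 1)
  fit <- train_network(net, data, training_config(epochs = 20, seed = 1))
  expect_gte(fit$history$accuracy[nrow(fit$history)], 0.95)
})

test_that("the surrogate slope shapes gradients only, never the forward pass", {
  data <- fixture_test_data()
  net <- build_network(fixture_arch(), neuron_config(), seed = 5)
  x <- snnmanifold:::index_batch(data$x, 1:4)
  f1 <- snnmanifold:::snn_forward(net, x, slope = 0.5)
  f2 <- snnmanifold:::snn_forward(net, x, slope = 25)
  expect_identical(f1$counts, f2$counts)
})

test_that("BPTT gradients match finite differences of the smoothed loss", {
  sf <- snnmanifold:::snn_forward
  sb <- snnmanifold:::snn_backward
  ce <- snnmanifold:::ce_loss
  set.seed(3)
  net <- build_network(architecture_spec("mlp", 5, 2, hidden = 3),
                       neuron_config(tau_m = 2, v_th = 1), seed = 2)
  x <- array(rbinom(3 * 4 * 5, 1, 0.4), c(3, 4, 5))
  y <- c(0L, 1L, 0L)
  loss_of <- function(n) {
    ce(sf(n, x, train_mode = TRUE, smooth = TRUE, slope = 2)$counts, y)$loss
  }
  fw <- sf(net, x, train_mode = TRUE, smooth = TRUE, slope = 2)
  gr <- sb(net, fw, ce(fw$counts, y)$dcounts, slope = 2)
  eps <- 1e-6
  for (l in 1:2) {
    w <- net$layers[[l]]$W
    for (i in sample(length(w), 5)) {
      n1 <- net; n1$layers[[l]]$W[i] <- w[i] + eps
      n2 <- net; n2$layers[[l]]$W[i] <- w[i] - eps
      fd <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
      expect_equal(gr[[l]]$dW[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("recurrence perturbs dynamics only through previous-step spikes", {
  cfg <- neuron_config(tau_m = 2, v_th = 0.6)
  base <- build_network(architecture_spec("mlp", 4, 2, hidden = 3), cfg, seed = 6)
  set.seed(9)
  x <- matrix(rbinom(24, 1, 0.5), 6, 4)

  # zero recurrent weights: outputs identical to the feedforward network
  rec0 <- add_recurrence(base, seed = 1)
  rec0$layers[[1]]$W_rec[] <- 0
  expect_equal(forward(rec0, x)$counts, forward(base, x)$counts)

  # nonzero recurrence changes the recurrent layer's own trajectory from the
  # step after its first spike onwards
  rec <- add_recurrence(base, seed = 1, sd = 2)
  out_ff <- forward(base, x, record = TRUE)
  out_rec <- forward(rec, x, record = TRUE)
  expect_gt(sum(out_ff$record[[1]]), 0)
  expect_false(identical(out_ff$record[[1]], out_rec$record[[1]]))

  # scalar oracle for a 2-neuron recurrent layer
  cfg2 <- neuron_config(tau_m = 2, v_th = 0.5)
  net2 <- build_network(architecture_spec("mlp", 2, 2, hidden = 2), cfg2, seed = 2)
  net2 <- add_recurrence(net2, seed = 3, sd = 1)
  x2 <- matrix(rbinom(12, 1, 0.6), 6, 2)
  got <- forward(net2, x2, record = TRUE)
  # independent loop with explicit recurrent term
  v1 <- c(0, 0); v2 <- c(0, 0); s_prev <- c(0, 0)
  ref_out <- matrix(0, 6, 2)
  for (t in 1:6) {
    z1 <- as.numeric(net2$layers[[1]]$W %*% x2[t, ]) + net2$layers[[1]]$b +
      as.numeric(net2$layers[[1]]$W_rec %*% s_prev)
    u1 <- (1 - cfg2$alpha) * v1 + z1
    s1 <- as.numeric(u1 >= cfg2$v_th)
    v1 <- ifelse(s1 == 1, 0, u1)
    s_prev <- s1
    z2 <- as.numeric(net2$layers[[2]]$W %*% s1) + net2$layers[[2]]$b
    u2 <- (1 - cfg2$alpha) * v2 + z2
    s2 <- as.numeric(u2 >= cfg2$v_th)
    v2 <- ifelse(s2 == 1, 0, u2)
    ref_out[t, ] <- s2
  }
  expect_equal(got$record[[2]], ref_out)
})

test_that("under the reset policy evaluation is order-invariant", {
  data <- fixture_test_data()
  net <- fixture_fit()$network
  ev1 <- evaluate_network(net, data, policy = "reset")
  ord <- rev(seq_along(data$labels))
  ev2 <- evaluate_network(net, data, policy = "reset", order = ord)
  expect_equal(ev1$accuracy, ev2$accuracy)
  expect_equal(ev1$predictions[ord], ev2$predictions)
})
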