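test_that("one-step membrane arithmetic matches the update rule", {
  # pure decay: v' = (1 - alpha) v
  cfg <- neuron_config(tau_m = 2, v_th = 10)
  st <- init_state(1, cfg)
  st$v <- 1.0
  r <- lif_step(st, 0, cfg)
  expect_equal(r$state$v, 0.5)
  expect_equal(r$spikes, 0)

  # hard reset clamps to v_reset at threshold crossing
  cfg_h <- neuron_config(tau_m = 2, v_th = 1, v_reset = 0)
  st <- init_state(1, cfg_h)
  st$v <- 0.9
  r <- lif_step(st, 0.6, cfg_h) # v_pre = 1.05
  expect_equal(r$spikes, 1)
  expect_identical(r$state$v, 0)

  # soft reset subtracts the threshold instead
  cfg_s <- neuron_config(tau_m = 2, v_th = 1, reset_mode = "soft")
  st <- init_state(1, cfg_s)
  st$v <- 0.9
  r <- lif_step(st, 0.6, cfg_s)
  expect_equal(r$state$v, 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(neuron_config(tau_m = 1, dt = 1), "tau_m")
  expect_error(neuron_config(v_th = 0, v_reset = 0), "v_th")
  expect_error(neuron_config(t_ref = -1), "t_ref")
  expect_error(neuron_config(t_ref = 1.5), "t_ref")
  expect_error(init_state(0, neuron_config()), "n_neurons")
  st <- init_state(2, neuron_config())
  expect_error(lif_step(st, c(1, Inf), neuron_config()), "non-finite")
  expect_error(lif_step(st, 1, neuron_config()), "size")
})

test_that("initial state sits exactly at the reset potential", {
  cfg <- neuron_config(v_reset = 0.2, v_th = 1)
  st <- init_state(3, cfg)
  expect_equal(st$v, rep(0.2, 3))
  expect_equal(st$refr, rep(0, 3))
  # no spontaneous spiking from rest when v_th > v_reset
  r <- lif_step(st, rep(0, 3), cfg)
  expect_equal(sum(r$spikes), 0)
})

test_that("zero-input membranes follow the (1 - alpha)^t closed form", {
  for (tau in c(1.5, 2, 3, 5, 10)) {
    cfg <- neuron_config(tau_m = tau, v_th = 100)
    st <- init_state(4, cfg)
    st$v <- c(0.3, -0.2, 0.9, 0.05)
    v0 <- st$v
    for (t in 1:50) {
      r <- lif_step(st, rep(0, 4), cfg)
      st <- r$state
      expect_equal(st$v, (1 - cfg$alpha)^t * v0, tolerance = 1e-12)
      expect_equal(sum(r$spikes), 0)
    }
  }
})

test_that("vectorized step equals the scalar per-neuron oracle bit-for-bit", {
  set.seed(101)
  for (rep in 1:100) {
    cfg <- neuron_config(
      tau_m = runif(1, 1.2, 6), v_th = runif(1, 0.2, 2),
      v_reset = 0, t_ref = sample(0:2, 1),
      reset_mode = sample(c("hard", "soft"), 1)
    )
    n <- 5
    currents <- matrix(rnorm(20 * n, sd = 0.8), 20, n)
    v0 <- runif(n, -0.5, cfg$v_th * 0.9)
    ref <- scalar_lif_trace(v0, currents, cfg)
    got <- vector_lif_trace(v0, currents, cfg)
    expect_identical(got$spikes, ref$spikes)
    expect_identical(got$v, ref$v)
  }
})

test_that("refractory neurons stay silent for exactly t_ref steps", {
  cfg <- neuron_config(tau_m = 2, v_th = 0.5, t_ref = 3L)
  st <- init_state(1, cfg)
  spikes <- numeric(10)
  for (t in 1:10) {
    r <- lif_step(st, 5, cfg) # strong constant drive
    st <- r$state
    spikes[t] <- r$spikes
  }
  # after each spike, exactly t_ref = 3 silent steps regardless of input
  expect_equal(spikes, c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0))
})

test_that("sample-boundary policies reset or preserve the state", {
  cfg <- neuron_config()
  st <- init_state(2, cfg)
  st$v <- c(0.3, 0.7)
  st$refr <- c(2, 0)
  st$last_spikes <- c(1, 0)

  carried <- apply_sample_boundary(st, "carry", cfg)
  expect_equal(carried$v, c(0.3, 0.7))
  expect_equal(carried$refr, c(2, 0))

  reset1 <- apply_sample_boundary(st, "reset", cfg)
  expect_equal(reset1$v, rep(cfg$v_reset, 2))
  expect_equal(reset1$refr, c(0, 0))
  expect_equal(reset1$last_spikes, c(0, 0))
  # reset is idempotent
  expect_identical(apply_sample_boundary(reset1, "reset", cfg), reset1)

  expect_error(apply_sample_boundary(st, "flush", cfg), "policy")
})
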