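test_that("mean firing rate averages spikes per neuron per timestep", {
  # two neurons, T = 4, trains (1,0,1,0) and (0,0,0,1)
  expect_equal(mean_firing_rate(list(cbind(c(1, 0, 1, 0), c(0, 0, 0, 1)))),
               0.375)
  expect_equal(mean_firing_rate(list(matrix(0, 5, 3), matrix(0, 5, 2))), 0)
  expect_equal(mean_firing_rate(list(matrix(1, 5, 3), matrix(1, 5, 2))), 1)
  # multi-sample records: [N x T x n] arrays, neurons weighted equally
  rec <- list(array(1, c(2, 4, 3)), array(0, c(2, 4, 5)))
  expect_equal(mean_firing_rate(rec), 3 / 8)
  expect_error(mean_firing_rate(list()), "Empty")
})

test_that("membership applies the rate band and the accuracy floor", {
  sweep <- tibble::tibble(
    tau_m = c(1, 2, 3), v_th = c(1, 1, 1),
    accuracy = c(0.95, 0.9, 0.99),
    mean_rate = c(0.001, 0.1, 0.9),
    total_spikes = 0, sop = 0
  )
  m <- manifold_membership(sweep, manifold_spec(r_min = 0.01, r_max = 0.5,
                                                a_thr = 0, a_thr_mode = "absolute"))
  expect_equal(as.logical(m), c(FALSE, TRUE, FALSE))

  # accuracy below the floor excludes an in-band point
  m2 <- manifold_membership(sweep, manifold_spec(r_min = 0.01, r_max = 0.5,
                                                 a_thr = 0.95, a_thr_mode = "absolute"))
  expect_equal(as.logical(m2), c(FALSE, FALSE, FALSE))

  # vacuous constraints admit everything
  m3 <- manifold_membership(sweep, manifold_spec(r_min = 0, r_max = 1,
                                                 a_thr = 0, a_thr_mode = "absolute"))
  expect_true(all(m3))

  # relative floor resolves against the observed maximum
  m4 <- manifold_membership(sweep, manifold_spec(r_min = 0, r_max = 1,
                                                 a_thr = 0.95))
  expect_equal(attr(m4, "a_floor"), 0.95 * 0.99)
})

test_that("boundary extraction matches exhaustive neighbour enumeration", {
  # 1 x 5 row: members adjacent to zeros are boundary, interior is not
  row <- matrix(c(FALSE, TRUE, TRUE, TRUE, FALSE), 1)
  expect_equal(as.logical(manifold_boundary(row)),
               c(FALSE, TRUE, FALSE, TRUE, FALSE))

  # all-true 3 x 3 grid: the edge rule marks the 8 rim cells
  full <- matrix(TRUE, 3, 3)
  b <- manifold_boundary(full)
  expect_false(b[2, 2])
  expect_equal(sum(b), 8)

  set.seed(77)
  for (i in 1:200) {
    mask <- matrix(runif(25) < 0.5, 5, 5)
    expect_identical(manifold_boundary(mask), brute_boundary(mask))
  }
})

test_that("boundary is always contained in the membership set", {
  set.seed(13)
  for (i in 1:50) {
    mask <- matrix(runif(30) < 0.4, 5, 6)
    b <- manifold_boundary(mask)
    expect_true(all(mask[b]))
  }
})

test_that("widening the membership bounds never shrinks the manifold", {
  set.seed(19)
  sweep <- tibble::tibble(
    tau_m = rep(1:5, each = 4), v_th = rep(1:4, 5),
    accuracy = runif(20), mean_rate = runif(20),
    total_spikes = 0, sop = 0
  )
  base <- manifold_membership(sweep, manifold_spec(0.2, 0.6, 0.5, "absolute"))
  wider_rate <- manifold_membership(sweep, manifold_spec(0.1, 0.8, 0.5, "absolute"))
  lower_floor <- manifold_membership(sweep, manifold_spec(0.2, 0.6, 0.2, "absolute"))
  expect_true(all(wider_rate[base]))
  expect_true(all(lower_floor[base]))
})

test_that("grid validation rejects degenerate axes", {
  expect_error(sweep_grid(tau_values = c(2, 1.5)), "increasing")
  expect_error(sweep_grid(tau_values = c(0.5, 2)), "tau_m")
  g <- sweep_grid(c(2, 3), c(0.5, 1))
  task <- sweep_task(fixture_test_data(), fixture_test_data(), fixture_arch())
  expect_error(run_sweep(task, g, mode = "eval_only"), "network")
})

test_that("a small sweep returns one finite row per grid point", {
  task <- make_static_task(synthetic_task_config(
    train_per_class = 10, test_per_class = 5, seed = 33
  ))
  st <- sweep_task(
    encode_dataset(task$train, 5, seed = 1),
    encode_dataset(task$test, 5, seed = 2),
    architecture_spec("mlp", 144, 4, hidden = 8)
  )
  g <- sweep_grid(c(1.5, 3), c(0.5, 1.5))
  sw <- run_sweep(st, g, train_config = training_config(n_steps = 5, epochs = 1,
                                                        batch_size = 8))
  expect_equal(nrow(sw), 4)
  expect_true(all(is.finite(sw$accuracy) & is.finite(sw$mean_rate) &
                    is.finite(sw$sop)))
  expect_true(all(sw$mean_rate >= 0 & sw$mean_rate <= 1))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))

  # eval_only re-evaluates one trained network under each configuration
  sw2 <- run_sweep(st, g, mode = "eval_only", network = fixture_fit())
  expect_equal(nrow(sw2), 4)

  mf <- manifold(sw, manifold_spec(0, 1, 0, "absolute"))
  expect_true(all(mf$sweep$in_manifold))
  expect_equal(glance(mf)$n_components, 1)
})

test_that("component counting distinguishes split masks", {
  expect_equal(n_components_4(matrix(c(TRUE, FALSE, TRUE), 1)), 2)
  expect_equal(n_components_4(matrix(TRUE, 2, 2)), 1)
  expect_equal(n_components_4(matrix(FALSE, 2, 2)), 0)
  # diagonal touch is not 4-connected
  expect_equal(n_components_4(diag(2) > 0), 2)
})
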