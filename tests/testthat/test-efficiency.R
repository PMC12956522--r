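test_that("SOP counting multiplies incoming spikes by the layer fan-out", {
  expect_equal(count_sop(matrix(c(3, 5), 1), fanout = 10), 80)
  expect_equal(count_sop(matrix(0, 3, 4), fanout = c(5, 7, 9)), 0)
  expect_error(count_sop(matrix(1, 2, 2), fanout = 5), "per layer")
  expect_error(count_sop(matrix(-1, 1, 1), fanout = 2), "non-negative")

  set.seed(41)
  for (i in 1:20) {
    incoming <- matrix(rpois(15, 4), 3, 5)
    fo <- sample(1:12, 3)
    expect_equal(count_sop(incoming, fo), brute_sop(incoming, fo))
  }
})

test_that("normalization maps observed extrema to [0, 1]", {
  expect_equal(min_max_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(min_max_normalize(c(5, 5)), c(0, 0))
  expect_equal(min_max_normalize(3), 0)
})

test_that("composite scores satisfy their defining identities", {
  expect_equal(bes(0.8, 0.4, lambda = 0.5), 0.6)
  a <- runif(5)
  expect_equal(bes(a, runif(5), lambda = 0), a)
  expect_equal(bes(0, 1, 1), -1)
  expect_error(bes(0.5, 0.5, lambda = 2), "lambda")

  for (b in c(1, 5)) expect_equal(eas(0.5, 0.5, beta = b), 0.5)
  expect_equal(eas(1, 0, beta = 0.3), 1)
  expect_equal(eas(0, 0.2, beta = 5), 0)
  expect_equal(eas(0, 1, beta = 5), 0) # 0/0 case defined as 0
  expect_error(eas(0.5, 0.5, beta = 0), "beta")
})

test_that("EAS is bounded, monotone, and accuracy-dominated at large beta", {
  set.seed(6)
  a <- runif(50); e <- runif(50)
  v <- eas(a, e, beta = 2)
  expect_true(all(v >= 0 & v <= 1))
  # monotone nondecreasing in a_norm
  expect_true(all(eas(pmin(a + 0.1, 1), e, 2) >= v - 1e-12))
  # and in 1 - e_norm
  expect_true(all(eas(a, pmax(e - 0.1, 0), 2) >= v - 1e-12))
  # beta -> infinity: EAS ranking converges to the accuracy ranking
  expect_equal(order(eas(a, e, beta = 1e3)), order(a))
})

test_that("BES decreases in lambda when energy is nonzero", {
  lams <- seq(0, 1, 0.1)
  vals <- sapply(lams, function(l) bes(0.7, 0.3, l))
  expect_true(all(diff(vals) < 0))
})

test_that("sweep scoring reports argmax points and the Pareto front", {
  sweep <- tibble::tibble(
    tau_m = rep(1:2, each = 2), v_th = rep(1:2, 2),
    accuracy = c(0.9, 0.5, 0.7, 0.2),
    mean_rate = 0.1, total_spikes = 1,
    sop = c(100, 500, 900, 400)
  )
  sc <- score_sweep(sweep, lambda = 0.5, beta = 5)
  # the first point dominates (max accuracy, min SOP): both argmaxes, sole front
  expect_equal(which.max(sc$bes), 1L)
  expect_equal(which.max(sc$eas), 1L)
  expect_equal(sc$pareto, c(TRUE, FALSE, FALSE, FALSE))

  # lambda = 0 makes the BES argmax the accuracy argmax
  sc0 <- score_sweep(sweep, lambda = 0, beta = 5)
  expect_equal(which.max(sc0$bes), which.max(sweep$accuracy))

  set.seed(23)
  rnd <- tibble::tibble(
    tau_m = 1:10, v_th = 1, accuracy = runif(10), mean_rate = 0.1,
    total_spikes = 1, sop = runif(10, 10, 1000)
  )
  scr <- score_sweep(rnd, 0.5, 5)
  expect_equal(scr$pareto, brute_pareto(scr$a_norm, scr$e_norm))
  expect_error(score_sweep(rnd[0, ]), "Empty")
})
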