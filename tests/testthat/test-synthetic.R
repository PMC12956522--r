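test_that("static task generation is a pure function of its config", {
  cfg <- synthetic_task_config(seed = 7)
  t1 <- make_static_task(cfg)
  t2 <- make_static_task(cfg)
  expect_identical(t1, t2)
  t3 <- make_static_task(synthetic_task_config(seed = 8))
  expect_false(identical(t1$train$images, t3$train$images))
})

test_that("zero noise collapses each class onto its template", {
  task <- make_static_task(synthetic_task_config(noise_sd = 0, seed = 3))
  by_class <- split(task$train$images, task$train$labels)
  for (imgs in by_class) {
    for (img in imgs) expect_identical(img, imgs[[1]])
  }
  # templates of different classes are distinct
  expect_gt(length(unique(task$templates)), 1)
})

test_that("generated intensities always satisfy the encoder preconditions", {
  task <- make_static_task(synthetic_task_config(noise_sd = 0.8, seed = 11))
  for (img in task$train$images[1:10]) {
    expect_true(all(img >= 0 & img <= 1))
    expect_silent(poisson_encode(img, 3, seed = 1))
  }
})

test_that("event task produces in-bounds streams with class structure", {
  et <- make_event_task(n_classes = 3, height = 8, width = 8,
                        noise_events = 0, seed = 4)
  expect_identical(et, make_event_task(n_classes = 3, height = 8, width = 8,
                                       noise_events = 0, seed = 4))
  for (s in et$train$streams[1:5]) {
    expect_true(all(s$x >= 0 & s$x <= 7 & s$y >= 0 & s$y <= 7))
    expect_true(all(s$t >= 0 & s$t <= et$duration))
    # binning conserves within-cell occupancy vs the raw count total
    b <- bin_events(s, 5, 8, 8, duration = et$duration, mode = "count")
    expect_equal(sum(b), nrow(s))
  }
})

test_that("common-input fraction controls pairwise correlation", {
  # c = 1: all trains copy the source, correlations are exactly 1
  s1 <- make_correlated_spike_trains(5, 200, p = 0.3, c = 1, seed = 2)
  cm <- correlation_matrix(s1)
  expect_true(all(abs(cm[upper.tri(cm)] - 1) < 1e-12))

  # c = 0: independent trains, negligible mean absolute correlation
  s0 <- make_correlated_spike_trains(6, 10000, p = 0.3, c = 0, seed = 2)
  cm0 <- correlation_matrix(s0)
  expect_lt(mean(abs(cm0[upper.tri(cm0)])), 0.05)

  # mean correlation grows monotonically in c (averaged over 10 seeds)
  cs <- c(0, 0.25, 0.5, 0.75, 1)
  mean_corr <- sapply(cs, function(cc) {
    mean(sapply(1:10, function(sd) {
      m <- correlation_matrix(
        make_correlated_spike_trains(8, 400, p = 0.3, c = cc, seed = sd)
      )
      mean(m[upper.tri(m)], na.rm = TRUE)
    }))
  })
  expect_true(all(diff(mean_corr) > 0))

  expect_error(make_correlated_spike_trains(4, 100, p = 0, c = 0.5, seed = 1),
               "p")
  expect_error(make_correlated_spike_trains(4, 100, p = 0.5, c = 2, seed = 1),
               "c")
})
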