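test_that("frame permutation preserves the multiset of frames", {
  set.seed(55)
  x <- matrix(rbinom(40, 1, 0.4), 10, 4)
  expect_identical(permute_frames(x, 0, seed = 1), x)
  for (k in c(1, 5, 30)) {
    xp <- permute_frames(x, k, seed = k)
    expect_equal(sum(xp), sum(x))
    expect_equal(sort(apply(xp, 1, paste, collapse = "")),
                 sort(apply(x, 1, paste, collapse = "")))
  }
  # T = 2 with one swap exchanges the two frames
  x2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(permute_frames(x2, 1, seed = 3), x2[2:1, ])
  expect_error(permute_frames(matrix(1, 1, 3), 1), "frames")
})

test_that("correlation matrices handle perfect, anti and absent correlation", {
  a <- c(1, 0, 1, 0)
  expect_equal(correlation_matrix(cbind(a, a))[1, 2], 1)
  expect_equal(correlation_matrix(cbind(a, 1 - a))[1, 2], -1)
  # zero-variance train: undefined pairs are NA
  cm <- correlation_matrix(cbind(a, rep(1, 4)))
  expect_true(is.na(cm[1, 2]))
  # independent long trains decorrelate
  s <- make_correlated_spike_trains(2, 10000, p = 0.3, c = 0, seed = 12)
  expect_lt(abs(correlation_matrix(s)[1, 2]), 0.05)
  expect_error(correlation_matrix(matrix(1, 1, 3)), "T >= 2")
})

test_that("correlation summaries compute the eight drift descriptors", {
  # constant coefficient c: mean = median = c, std = 0
  m <- matrix(0.8, 4, 4); diag(m) <- 1
  s <- summarize_correlations(m)
  expect_equal(s$mean, 0.8)
  expect_equal(s$median, 0.8)
  expect_equal(s$std, 0)
  expect_equal(s$n_gt_075, 6)
  expect_equal(s$n_gt_090, 0)

  # hand-placed coefficients: (0.8, 0.95, 0.2)
  m2 <- diag(3)
  m2[1, 2] <- m2[2, 1] <- 0.8
  m2[1, 3] <- m2[3, 1] <- 0.95
  m2[2, 3] <- m2[3, 2] <- 0.2
  s2 <- summarize_correlations(m2)
  expect_equal(s2$n_gt_075, 2)
  expect_equal(s2$n_gt_090, 1)
  expect_equal(s2$p99, unname(quantile(c(0.8, 0.95, 0.2), 0.99)))

  # symmetric distributions have zero skewness
  vals <- c(-0.4, -0.2, 0, 0.2, 0.4, -0.3, 0.3, -0.1, 0.1, 0)
  m3 <- diag(5)
  m3[upper.tri(m3)] <- vals
  m3[lower.tri(m3)] <- t(m3)[lower.tri(m3)]
  expect_equal(summarize_correlations(m3)$skewness, 0, tolerance = 1e-12)

  expect_error(summarize_correlations(matrix(NA_real_, 2, 2)), "undefined")
})

test_that("correlation matrices from activity are symmetric with unit diagonal", {
  set.seed(9)
  for (i in 1:10) {
    s <- make_correlated_spike_trains(6, 50, p = 0.3, c = runif(1), seed = i)
    cm <- correlation_matrix(s)
    expect_equal(cm, t(cm))
    defined <- !is.na(diag(cm))
    expect_true(all(diag(cm)[defined] == 1))
  }
})

test_that("mutual information is 1 bit for a label copy and 0 for a constant", {
  lab <- rep(c("clean", "noisy"), each = 500)
  f <- tibble::tibble(
    copy = as.numeric(lab == "noisy"),
    flat = rep(1, 1000)
  )
  mi <- mutual_information_scores(f, lab)
  expect_equal(mi$mi_bits[mi$feature == "copy"], 1)
  expect_equal(mi$mi_bits[mi$feature == "flat"], 0)

  # independent feature: MI near zero at n = 2000
  set.seed(2)
  lab2 <- rep(c("clean", "noisy"), each = 1000)
  mi2 <- mutual_information_scores(tibble::tibble(x = rnorm(2000)), lab2)
  expect_lt(mi2$mi_bits, 0.02)
  expect_error(mutual_information_scores(f, rep("clean", 1000)), "two classes")
})

test_that("the condition classifier separates separable features", {
  set.seed(4)
  n <- 200
  f <- tibble::tibble(a = c(rnorm(n, 0), rnorm(n, 6)), b = rnorm(2 * n))
  lab <- rep(c("clean", "noisy"), each = n)
  clf <- condition_classifier(f, lab, seed = 5)
  expect_equal(clf$accuracy, 1.0)
  expect_equal(sum(clf$importance$gain), 1)
  expect_gt(clf$importance$gain[clf$importance$feature == "a"], 0.9)
  expect_error(condition_classifier(f, rep("x", 2 * n)), "two classes")
})

test_that("pair collection respects the gates of the flip protocol", {
  # robust "network": constant input over time can never flip under
  # permutation, so every correct sample is discarded at max_level
  fit <- fixture_fit()
  task <- fixture_task()
  const_img <- task$test$images[[1]] * 0 + 0.5
  xc <- poisson_encode(matrix(0.5, 12, 12) * 0 + 1, 10, seed = 1) # all-ones
  x <- array(0, c(2, 10, 144))
  x[1, , ] <- xc
  x[2, , ] <- xc
  pred1 <- predict_label(forward(fit$network, xc)$counts)
  data_const <- list(x = x, labels = rep(as.integer(pred1), 2))
  pp <- collect_pairs(fit, data_const, perturbation_config(seed = 1))
  expect_equal(length(pp$pairs), 0)
  expect_equal(pp$discarded, 2)

  # misclassified clean samples are skipped, never perturbed
  data_wrong <- list(x = x, labels = rep(as.integer(pred1) + 1L, 2) %% 4L)
  pp2 <- collect_pairs(fit$network, data_wrong, perturbation_config(seed = 1))
  expect_equal(pp2$skipped, 2)
  expect_equal(length(pp2$pairs), 0)

  # termination: never more than max_level rounds per sample
  expect_lte(pp$max_level, 3 * 10)
})

test_that("per-sample feature tables carry both conditions", {
  clean <- lapply(1:10, function(i) {
    make_correlated_spike_trains(8, 50, 0.3, 0, seed = i)
  })
  noisy <- lapply(1:10, function(i) {
    make_correlated_spike_trains(8, 50, 0.3, 0.8, seed = 100 + i)
  })
  ft <- correlation_feature_table(clean, noisy)
  expect_true(all(c("mean", "kurtosis", "n_gt_090", "condition") %in% names(ft)))
  expect_equal(sort(unique(ft$condition)), c("clean", "noisy"))
  agg <- dplyr::summarise(dplyr::group_by(ft, condition),
                          m = mean(mean))
  expect_gt(agg$m[agg$condition == "noisy"], agg$m[agg$condition == "clean"])
})
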