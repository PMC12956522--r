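# Perturbation collection and correlation-based drift diagnostics: frame
# permutations that progressively disorder the input, clean/perturbed
# activity pairs at the first prediction flip, pairwise Pearson correlation
# summaries, mutual-information ranking and a gradient-boosted-tree
# clean-vs-noisy classifier.

#' Randomly permute time frames of a spike tensor
#'
#' Applies `n_swaps` independent uniformly random transpositions of whole
#' time frames to the clean input. The multiset of frames (and hence the
#' total spike count) is preserved; only their order is disturbed.
#'
#' @param x A spike tensor with time as its first dimension (T >= 2).
#' @param n_swaps Number of transpositions (>= 0).
#' @param seed Optional integer seed; `NULL` draws from the current RNG.
#' @return The permuted tensor.
#' @export
permute_frames <- function(x, n_swaps, seed = NULL) {
  d <- dim(x)
  t_steps <- d[1]
  if (t_steps < 2L) rlang::abort("Need at least 2 time frames to permute.")
  stopifnot(n_swaps >= 0)
  draw <- function() {
    perm <- seq_len(t_steps)
    for (k in seq_len(n_swaps)) {
      ij <- sample.int(t_steps, 2L)
      perm[ij] <- perm[rev(ij)]
    }
    perm
  }
  perm <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  idx <- as.list(rep(TRUE, length(d)))
  idx[[1]] <- perm
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Perturbation collection settings
#'
#' @param max_pairs Stop after this many correct-to-incorrect activity pairs
#'   (default 2000).
#' @param swap_increment Swaps added per perturbation round (default 1).
#' @param max_level Cap on cumulative swaps per sample; default `3 * T`,
#'   resolved at collection time when `NULL`.
#' @param seed Integer seed for the permutation draws.
#' @return A classed list.
#' @export
perturbation_config <- function(max_pairs = 2000, swap_increment = 1,
                                max_level = NULL, seed = 1) {
  stopifnot(max_pairs >= 1, swap_increment >= 1,
            is.null(max_level) || max_level >= 1)
  structure(list(max_pairs = as.integer(max_pairs),
                 swap_increment = as.integer(swap_increment),
                 max_level = if (is.null(max_level)) NULL else as.integer(max_level),
                 seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Collect clean/perturbed activity pairs at the first prediction flip
#'
#' For every test sample the network classifies correctly on the clean input
#' (state reset before each evaluation), the input is progressively
#' disordered: at round k the clean tensor receives `k * swap_increment`
#' random frame transpositions (a fresh permutation each round), and the
#' sample is re-evaluated, until the prediction flips from correct to
#' incorrect. At the flip, the clean and perturbed activities of the final
#' hidden spiking layer are stored together with the swap count
#' (`flip_level`). Samples that never flip within `max_level` swaps are
#' discarded; misclassified clean samples are skipped outright. Collection
#' stops at `max_pairs` pairs or dataset exhaustion.
#'
#' @param network A trained `snn_network` or `snn_fit`.
#' @param data An encoded dataset from [encode_dataset()].
#' @param config A [perturbation_config()].
#' @return A list of class `perturbation_pairs`: `pairs` (each with
#'   `clean_activity` and `perturbed_activity` `[T x n]` matrices of the
#'   final hidden spiking layer, `label`, `flip_level`), plus counts of
#'   samples `skipped` (clean miss) and `discarded` (never flipped).
#' @export
collect_pairs <- function(network, data, config = perturbation_config()) {
  if (inherits(network, "snn_fit")) network <- network$network
  stopifnot(inherits(network, "snn_network"),
            inherits(config, "perturbation_config"))
  n <- dim(data$x)[1]
  t_steps <- dim(data$x)[2]
  max_level <- if (is.null(config$max_level)) 3L * t_steps else config$max_level
  layer_idx <- length(network$layers) - 1L # final hidden spiking layer
  pairs <- list()
  skipped <- 0L
  discarded <- 0L
  withr::with_seed(config$seed, {
    for (i in seq_len(n)) {
      if (length(pairs) >= config$max_pairs) break
      xi <- index_batch(data$x, i)
      clean <- snn_forward(network, xi, record = TRUE)
      pred <- predict_label(drop(clean$counts))
      if (pred != data$labels[i]) {
        skipped <- skipped + 1L
        next
      }
      x1 <- array(xi, dim(xi)[-1])
      level <- 0L
      flipped <- FALSE
      while (level + config$swap_increment <= max_level) {
        level <- level + config$swap_increment
        xp <- permute_frames(x1, level) # clean input plus `level` fresh swaps
        pert <- snn_forward(network, array(xp, c(1L, dim(xp))), record = TRUE)
        if (predict_label(drop(pert$counts)) != data$labels[i]) {
          take <- function(fw) {
            r <- fw$record[[layer_idx]]
            matrix(r[1, , ], dim(r)[2], dim(r)[3])
          }
          pairs[[length(pairs) + 1L]] <- list(
            clean_activity = take(clean),
            perturbed_activity = take(pert),
            label = data$labels[i], flip_level = level
          )
          flipped <- TRUE
          break
        }
      }
      if (!flipped) discarded <- discarded + 1L
    }
  })
  structure(list(pairs = pairs, skipped = skipped, discarded = discarded,
                 t_steps = t_steps, max_level = max_level),
            class = "perturbation_pairs")
}

#' @export
print.perturbation_pairs <- function(x, ...) {
  cat(sprintf(
    "<perturbation_pairs> %d pairs (skipped %d clean misses, %d never flipped)\n",
    length(x$pairs), x$skipped, x$discarded
  ))
  invisible(x)
}

#' Pairwise Pearson correlation matrix of spike trains
#'
#' Correlates every pair of neuronal spike trains in a `[T x n]` activity
#' matrix. Pairs involving a zero-variance (constant) train are undefined
#' and returned as `NA`; downstream summaries exclude them. The diagonal is
#' 1 wherever defined.
#'
#' @param activity A binary (or numeric) `[T x n]` matrix, T >= 2, n >= 2.
#' @return An `n x n` correlation matrix with `NA` for undefined pairs.
#' @examples
#' correlation_matrix(cbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
#' @export
correlation_matrix <- function(activity) {
  if (nrow(activity) < 2L) rlang::abort("Need T >= 2 timesteps.")
  if (ncol(activity) < 2L) rlang::abort("Need at least 2 neurons.")
  suppressWarnings(stats::cor(activity))
}

#' Summary statistics of a correlation distribution
#'
#' The eight drift descriptors extracted from the upper triangle of a
#' correlation matrix (excluding the diagonal and undefined pairs): mean,
#' median, standard deviation, skewness (standardized third central moment),
#' excess kurtosis, 99th percentile (linear interpolation) and the counts of
#' coefficients exceeding 0.75 and 0.9.
#'
#' When given a list of per-sample matrices, they are first averaged
#' elementwise into one condition-averaged matrix (undefined pairs are
#' dropped from the average where possible) unless `per_sample = TRUE`, in
#' which case one row of statistics is returned per matrix.
#'
#' @param x A correlation matrix or a list of correlation matrices.
#' @param per_sample If `TRUE` and `x` is a list, summarize each matrix
#'   separately (one tibble row each) instead of averaging first.
#' @return A tibble with columns `mean`, `median`, `std`, `skewness`,
#'   `kurtosis`, `p99`, `n_gt_075`, `n_gt_090`, plus `n_pairs` (defined
#'   pairs summarized) and `n_excluded` (undefined pairs).
#' @export
summarize_correlations <- function(x, per_sample = FALSE) {
  if (is.list(x) && per_sample) {
    return(dplyr::bind_rows(lapply(x, summarize_correlations)))
  }
  if (is.list(x)) {
    arr <- array(unlist(x), c(dim(x[[1]]), length(x)))
    x <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    x[is.nan(x)] <- NA_real_
  }
  ut <- x[upper.tri(x)]
  n_excluded <- sum(is.na(ut))
  v <- ut[!is.na(ut)]
  if (length(v) == 0L) {
    rlang::abort("All correlation pairs are undefined (degenerate activity).")
  }
  tibble::tibble(
    mean = mean(v), median = stats::median(v), std = stats::sd(v),
    skewness = if (length(v) > 2 && stats::sd(v) > 0) {
      e1071::skewness(v, type = 1)
    } else 0,
    kurtosis = if (length(v) > 3 && stats::sd(v) > 0) {
      e1071::kurtosis(v, type = 1)
    } else 0,
    p99 = unname(stats::quantile(v, 0.99, type = 7)),
    n_gt_075 = sum(v > 0.75), n_gt_090 = sum(v > 0.9),
    n_pairs = length(v), n_excluded = n_excluded
  )
}

corr_feature_names <- c("mean", "median", "std", "skewness", "kurtosis",
                        "p99", "n_gt_075", "n_gt_090")

#' Per-sample correlation feature table for two conditions
#'
#' Builds the clean-vs-noisy feature dataset: one row per activity sample,
#' the eight correlation summary statistics as features and the condition as
#' label.
#'
#' @param clean,noisy Lists of `[T x n]` activity matrices.
#' @return A tibble with the eight feature columns and a `condition` column
#'   (`"clean"` / `"noisy"`). Samples whose correlation pairs are all
#'   undefined are dropped.
#' @export
correlation_feature_table <- function(clean, noisy) {
  row_of <- function(a, cond) {
    cm <- correlation_matrix(a)
    if (all(is.na(cm[upper.tri(cm)]))) {
      return(NULL)
    }
    s <- summarize_correlations(cm)
    s$condition <- cond
    s
  }
  dplyr::bind_rows(
    purrr::compact(purrr::map(clean, row_of, cond = "clean")),
    purrr::compact(purrr::map(noisy, row_of, cond = "noisy"))
  )[c(corr_feature_names, "condition")]
}

#' Mutual information between each feature and a binary condition
#'
#' Each feature is quantile-binned (default 10 bins, deterministic and
#' seedless) and its mutual information with the binary label computed in
#' bits. A feature identical to a balanced binary label scores 1 bit; a
#' constant feature scores 0.
#'
#' @param features A data frame of numeric features.
#' @param labels A binary condition vector (two levels, both present).
#' @param bins Number of quantile bins (default 10).
#' @return A tibble with columns `feature` and `mi_bits`, sorted decreasing.
#' @export
mutual_information_scores <- function(features, labels, bins = 10) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    rlang::abort("`labels` must contain exactly two classes.")
  }
  mi_one <- function(x) {
    brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                  type = 7))
    if (length(brk) < 2L) {
      return(0)
    }
    bx <- cut(x, breaks = brk, include.lowest = TRUE)
    tab <- table(bx, labels)
    p <- tab / sum(tab)
    px <- rowSums(p)
    py <- colSums(p)
    sum(ifelse(p > 0, p * log2(p / outer(px, py)), 0))
  }
  out <- tibble::tibble(
    feature = names(features),
    mi_bits = unname(purrr::map_dbl(features, mi_one))
  )
  dplyr::arrange(out, dplyr::desc(.data$mi_bits))
}

#' Gradient-boosted clean-vs-noisy condition classifier
#'
#' Fits an xgboost tree ensemble on the correlation summary features with a
#' seeded stratified 80/20 train/test split, and reports held-out accuracy
#' together with normalized (gain) feature importances summing to 1.
#'
#' @param features A data frame of numeric features (the eight correlation
#'   statistics).
#' @param labels Binary condition labels (two levels, >= 2 samples each).
#' @param seed Integer seed for the split and the ensemble.
#' @param train_frac Training fraction of the stratified split (default 0.8).
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @return A list of class `condition_classifier`: `accuracy` (held-out),
#'   `importance` (tibble `feature`, `gain`), `n_train`, `n_test`.
#' @export
condition_classifier <- function(features, labels, seed = 1, train_frac = 0.8,
                                 nrounds = 60, max_depth = 3, eta = 0.3) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 2L)) {
    rlang::abort("Need two classes with at least 2 samples each.")
  }
  X <- as.matrix(features)
  y <- as.integer(labels) - 1L
  idx_tr <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      sample(ix, max(1L, floor(train_frac * length(ix))))
    }), use.names = FALSE)
  })
  idx_te <- setdiff(seq_along(y), idx_tr)
  if (length(idx_te) < 1L) rlang::abort("Degenerate split: no held-out samples.")
  fit <- xgboost::xgboost(
    x = X[idx_tr, , drop = FALSE], y = factor(y[idx_tr], levels = c(0, 1)),
    nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
    objective = "binary:logistic", nthreads = 1, verbosity = 0,
    seed = as.integer(seed)
  )
  prob <- stats::predict(fit, X[idx_te, , drop = FALSE], type = "response")
  pred <- as.integer(prob > 0.5)
  imp <- xgboost::xgb.importance(model = fit)
  gain <- stats::setNames(rep(0, ncol(X)), colnames(X))
  gain[imp$Feature] <- imp$Gain
  gain <- gain / sum(gain)
  structure(
    list(
      accuracy = mean(pred == y[idx_te]),
      importance = tibble::tibble(feature = names(gain), gain = unname(gain)),
      n_train = length(idx_tr), n_test = length(idx_te)
    ),
    class = "condition_classifier"
  )
}

#' @export
print.condition_classifier <- function(x, ...) {
  cat(sprintf("<condition_classifier> held-out accuracy %.3f (%d train / %d test)\n",
              x$accuracy, x$n_train, x$n_test))
  invisible(x)
}
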