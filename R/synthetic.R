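# Seeded synthetic task generators. These stand in for static-image and
# event-camera benchmarks at desk scale: each class is a distinct spatial
# template (oriented bar) or moving-edge trajectory, so tasks are separable by
# construction and every downstream stage is testable without any download.

#' Configuration for a synthetic static-image task
#'
#' @param n_classes Number of classes (>= 2).
#' @param height,width Image dimensions in pixels.
#' @param train_per_class,test_per_class Samples per class in each split.
#' @param contrast Template intensity in `(0, 1]`.
#' @param noise_sd Gaussian pixel-noise standard deviation (intensities are
#'   clipped back to `[0, 1]`).
#' @param seed Integer seed; the generator is a pure function of this config.
#' @return A classed list of settings.
#' @export
synthetic_task_config <- function(n_classes = 4, height = 12, width = 12,
                                  train_per_class = 40, test_per_class = 20,
                                  contrast = 0.4, noise_sd = 0.35, seed = 42) {
  stopifnot(n_classes >= 2, height >= 3, width >= 3,
            train_per_class >= 1, test_per_class >= 1,
            contrast > 0, contrast <= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_task_config")
}

# Oriented-bar template for one class: a 2-pixel-wide bar through a
# class-specific anchor at a class-specific angle.
class_template <- function(k, n_classes, height, width, contrast) {
  tmpl <- matrix(0, height, width)
  angle <- (k - 1) * pi / n_classes
  cy <- height / 2 + 0.25 * height * cos(2 * pi * (k - 1) / n_classes)
  cx <- width / 2 + 0.25 * width * sin(2 * pi * (k - 1) / n_classes)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      d <- abs((r - cy) * cos(angle) - (c - cx) * sin(angle))
      if (d <= 1) tmpl[r, c] <- contrast
    }
  }
  tmpl
}

#' Generate a synthetic static-image classification task
#'
#' Each class is assigned a distinct oriented-bar template (distinct angle and
#' anchor); samples are the template plus i.i.d. Gaussian pixel noise, clipped
#' to `[0, 1]`. At zero noise the classes are linearly separable. The output
#' images feed [poisson_encode()] directly.
#'
#' @param config A [synthetic_task_config()].
#' @return A list with class `static_task`: `train` and `test`, each a list of
#'   `images` (list of `height x width` matrices) and `labels` (integer class
#'   ids in `0:(n_classes-1)`), plus `templates` and the `config`.
#' @examples
#' task <- make_static_task(synthetic_task_config(n_classes = 2, seed = 1))
#' length(task$train$images)
#' @export
make_static_task <- function(config = synthetic_task_config()) {
  stopifnot(inherits(config, "synthetic_task_config"))
  templates <- lapply(seq_len(config$n_classes), function(k) {
    class_template(k, config$n_classes, config$height, config$width,
                   config$contrast)
  })
  draw_split <- function(per_class, seed) {
    withr::with_seed(seed, {
      labels <- rep(seq_len(config$n_classes) - 1L, each = per_class)
      ord <- sample(length(labels))
      labels <- labels[ord]
      images <- lapply(labels, function(lab) {
        img <- templates[[lab + 1L]] +
          matrix(stats::rnorm(config$height * config$width,
                              sd = config$noise_sd),
                 config$height, config$width)
        pmin(pmax(img, 0), 1)
      })
      list(images = images, labels = labels)
    })
  }
  structure(
    list(
      train = draw_split(config$train_per_class, as.integer(config$seed)),
      test = draw_split(config$test_per_class, as.integer(config$seed) + 1L),
      templates = templates,
      config = config
    ),
    class = "static_task"
  )
}

#' Generate a synthetic event-stream classification task
#'
#' Emulates DVS-style recordings with class structure: class `k` is a moving
#' edge sweeping the frame along a class-specific direction, emitting
#' polarity-1 events on its leading edge and polarity-0 events on its trailing
#' edge, plus uniform background noise events of random polarity.
#'
#' @param n_classes Number of classes (>= 2).
#' @param duration Recording duration per sample (arbitrary time units).
#' @param height,width Frame dimensions in pixels.
#' @param events_per_sample Number of signal events per sample (>= 1).
#' @param noise_events Number of uniform background events per sample.
#' @param train_per_class,test_per_class Samples per class in each split.
#' @param seed Integer seed.
#' @return A list with class `event_task`: `train`/`test` splits holding
#'   `streams` (list of [event_stream()]) and `labels`, plus the settings.
#' @export
make_event_task <- function(n_classes = 2, duration = 1, height = 8, width = 8,
                            events_per_sample = 60, noise_events = 10,
                            train_per_class = 30, test_per_class = 10,
                            seed = 42) {
  stopifnot(n_classes >= 2, height >= 2, width >= 2, events_per_sample >= 1,
            noise_events >= 0, duration > 0)
  one_sample <- function(lab) {
    angle <- 2 * pi * lab / n_classes
    dir <- c(cos(angle), sin(angle)) # (dx, dy) of the sweeping edge
    tt <- sort(stats::runif(events_per_sample, 0, duration))
    frac <- tt / duration
    # edge position sweeps across the frame; events scatter along the edge
    cx <- (0.15 + 0.7 * frac) * (width - 1) * abs(dir[1]) +
      stats::runif(events_per_sample, 0, 0.3) * (width - 1) * (1 - abs(dir[1]))
    cy <- (0.15 + 0.7 * frac) * (height - 1) * abs(dir[2]) +
      stats::runif(events_per_sample, 0, 0.3) * (height - 1) * (1 - abs(dir[2]))
    jitter <- stats::runif(events_per_sample, -0.5, 0.5)
    x <- round(pmin(pmax(cx + jitter, 0), width - 1))
    y <- round(pmin(pmax(cy + jitter, 0), height - 1))
    p <- as.integer(stats::runif(events_per_sample) < 0.5 + 0.4 * sign(dir[1]))
    if (noise_events > 0) {
      tt <- c(tt, stats::runif(noise_events, 0, duration))
      x <- c(x, sample.int(width, noise_events, replace = TRUE) - 1L)
      y <- c(y, sample.int(height, noise_events, replace = TRUE) - 1L)
      p <- c(p, sample(c(0L, 1L), noise_events, replace = TRUE))
    }
    ord <- order(tt)
    event_stream(tt[ord], x[ord], y[ord], p[ord])
  }
  draw_split <- function(per_class, split_seed) {
    withr::with_seed(split_seed, {
      labels <- rep(seq_len(n_classes) - 1L, each = per_class)
      ord <- sample(length(labels))
      labels <- labels[ord]
      list(streams = lapply(labels, one_sample), labels = labels)
    })
  }
  structure(
    list(
      train = draw_split(train_per_class, as.integer(seed)),
      test = draw_split(test_per_class, as.integer(seed) + 1L),
      n_classes = n_classes, duration = duration,
      height = height, width = width, seed = seed
    ),
    class = "event_task"
  )
}

#' Generate correlated binary spike trains
#'
#' A common-input mixture: at every timestep each neuron either copies a
#' shared source train of rate `p` (with probability `c`) or makes an
#' independent Bernoulli(`p`) draw. `c = 0` yields independent trains,
#' `c = 1` identical trains; expected pairwise correlation grows
#' monotonically with `c`.
#'
#' @param n_neurons Number of trains (>= 2).
#' @param t_steps Train length T.
#' @param p Firing rate per step, in `(0, 1)`.
#' @param c Common-input fraction, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A binary `[t_steps x n_neurons]` spike matrix.
#' @examples
#' s <- make_correlated_spike_trains(5, 100, p = 0.2, c = 0.5, seed = 1)
#' mean(s)
#' @export
make_correlated_spike_trains <- function(n_neurons, t_steps, p, c, seed) {
  if (!(p > 0 && p < 1)) rlang::abort("`p` must lie in (0, 1).")
  if (!(c >= 0 && c <= 1)) rlang::abort("`c` must lie in [0, 1].")
  stopifnot(n_neurons >= 2, t_steps >= 2)
  withr::with_seed(as.integer(seed), {
    source <- stats::rbinom(t_steps, 1, p)
    own <- matrix(stats::rbinom(t_steps * n_neurons, 1, p), t_steps, n_neurons)
    gate <- matrix(stats::rbinom(t_steps * n_neurons, 1, c), t_steps, n_neurons)
    gate * source + (1 - gate) * own
  })
}
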